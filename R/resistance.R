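## Clot constitutive laws: deposition- and fibrin-dependent inverse
## permeability, and the surface-to-volume clot propagation rule.

#' Platelet contribution to the clot hydraulic resistance
#'
#' `1/G_DP = 1/G_DP_max * phi^2 / (phi_cri^2 + phi^2)`; half-maximal at
#' `phi = phi_cri`.
#'
#' @param phi deposited-platelet coverage fraction in \[0, 1]
#' @param params [clot_parameters()]
#' @return inverse permeability, 1/m2 (vectorized)
#' @export
platelet_inverse_permeability <- function(phi, params = clot_parameters()) {
  stopifnot(all(phi >= 0), all(phi <= 1))
  params$inv_g_dp_max * phi^2 / (params$phi_cri^2 + phi^2)
}

#' Fibrin contribution to the clot hydraulic resistance
#'
#' Davis fibrous-media relation for a network of fibers of radius `r_f`:
#' `1/G_F = 16 psi^1.5 (1 + 56 psi^3) / r_f^2`.
#'
#' @param psi fibrin volume indicator: ratio of fibrin to the reference
#'   fibrinogen concentration, in \[0, 1]
#' @param r_f fiber radius, m
#' @return inverse permeability, 1/m2 (vectorized)
#' @export
fibrin_inverse_permeability <- function(psi, r_f = clot_parameters()$r_f) {
  stopifnot(all(psi >= 0), all(psi <= 1))
  16 * psi^1.5 * (1 + 56 * psi^3) / r_f^2
}

#' Fibrin fraction from local fibrin concentration
#'
#' The ratio of fibrin to the inlet fibrinogen concentration, clamped
#' at 1 (total conversion).
#'
#' @param c_f fibrin concentration, uM
#' @param c_fg_ref reference (inlet) fibrinogen concentration, uM
#' @return psi in \[0, 1]
#' @export
fibrin_fraction <- function(c_f, c_fg_ref) {
  stopifnot(c_fg_ref > 0)
  pmin(1, pmax(0, c_f / c_fg_ref))
}

#' Total clot inverse permeability
#'
#' @param inv_g_dp platelet component, 1/m2
#' @param inv_g_f fibrin component, 1/m2
#' @return their sum, 1/m2
#' @export
total_inverse_permeability <- function(inv_g_dp, inv_g_f) {
  stopifnot(all(inv_g_dp >= 0), all(inv_g_f >= 0))
  inv_g_dp + inv_g_f
}

#' Create an empty per-cell resistance field
#'
#' @param mesh a `clot_mesh`
#' @return list of class `resistance_field`: per-cell `inv_g_dp`,
#'   `inv_g_f`, `inv_g_clot`, per-cell coverage `phi_cell` and the clot
#'   indicator mask
#' @export
resistance_field <- function(mesh) {
  n <- mesh$n_cells
  structure(list(
    inv_g_dp = numeric(n), inv_g_f = numeric(n), inv_g_clot = numeric(n),
    phi_cell = numeric(n), clot = logical(n)
  ), class = "resistance_field")
}

## Active deposition faces: a data.frame with the mesh face columns plus
## dynamic phi/q bookkeeping handled by the deposition state. Faces are
## identified by (cell, side).
active_face_key <- function(faces) paste(faces$cell, faces$side)

#' Update the resistance field and propagate the clot surface
#'
#' Face coverage maps onto the adjacent cell (a cell's coverage is the
#' maximum over its active faces). A cell whose coverage reaches
#' `phi_full` is marked clot permanently; its fluid-facing sides become
#' fresh deposition surfaces (coverage 0), which is how the thrombus
#' grows into the lumen. The per-cell inverse permeability combines the
#' platelet law on the coverage with the Davis fibrin term on the local
#' fibrin fraction; clot-marked cells keep at least their marking-time
#' platelet resistance.
#'
#' @param resist a `resistance_field`
#' @param active data.frame of active deposition faces (columns `cell`,
#'   `side`, `i`, `j`, plus mesh face metadata)
#' @param dep a `wall_deposition_state` aligned with `active`
#' @param mesh the `clot_mesh`
#' @param c_f per-cell fibrin concentration, uM (or `NULL`)
#' @param c_fg_ref reference fibrinogen, uM
#' @param params [clot_parameters()]
#' @return list: updated `resist`, `active`, `dep` (with any newly
#'   exposed faces appended at coverage 0) and the number of new clot cells
#' @export
propagate_clot <- function(resist, active, dep, mesh, c_f = NULL,
                           c_fg_ref = blood_concentrations()[["fg"]],
                           params = clot_parameters()) {
  n <- mesh$n_cells
  ## face coverage -> adjacent cell coverage (max over the cell's faces)
  phi_cell <- numeric(n)
  if (nrow(active)) {
    agg <- tapply(dep$phi, active$cell, max)
    phi_cell[as.integer(names(agg))] <- as.numeric(agg)
  }
  ## clot cells are permanent; keep their peak coverage
  resist$phi_cell <- pmax(ifelse(resist$clot, resist$phi_cell, 0), phi_cell)
  ## current resistance components (fibrin needs a platelet scaffold)
  inv_dp <- platelet_inverse_permeability(pmin(1, resist$phi_cell), params)
  scaffold <- resist$phi_cell >= params$phi_scaffold | resist$clot
  inv_f <- numeric(n)
  if (!is.null(c_f) && any(scaffold))
    inv_f[scaffold] <- fibrin_inverse_permeability(
      fibrin_fraction(c_f[scaffold], c_fg_ref), params$r_f)
  inv_tot <- total_inverse_permeability(inv_dp, inv_f)
  ## a cell joins the clot when its coverage saturates or when it has
  ## become effectively solid, so the deposition surface advances to its
  ## fluid-facing sides
  newly <- which(!resist$clot &
                   (resist$phi_cell >= params$phi_full |
                      inv_tot >= params$solidify_frac * params$inv_g_dp_max))
  resist$clot[newly] <- TRUE

  ## expose fluid-facing sides of new clot cells as fresh surfaces
  if (length(newly)) {
    cid <- mesh$cell_id; fl <- mesh$fluid
    ci <- mesh$cells$i[newly]; cj <- mesh$cells$j[newly]
    cand <- list()
    sides <- list(W = c(-1L, 0L), E = c(1L, 0L), S = c(0L, -1L), N = c(0L, 1L))
    opp <- c(W = "E", E = "W", S = "N", N = "S")
    for (sd in names(sides)) {
      off <- sides[[sd]]
      ii <- ci + off[1]; jj <- cj + off[2]
      ok <- ii >= 1 & ii <= mesh$nx & jj >= 1 & jj <= mesh$ny
      ok[ok] <- fl[cbind(ii[ok], jj[ok])]
      if (!any(ok)) next
      nb <- cid[cbind(ii[ok], jj[ok])]
      open <- !resist$clot[nb]
      if (!any(open)) next
      ## the new surface lives on the *neighbor* cell, facing the clot
      cand[[sd]] <- data.frame(
        cell = nb[open], i = ii[ok][open], j = jj[ok][open],
        side = opp[[sd]], stringsAsFactors = FALSE
      )
    }
    cand <- do.call(rbind, cand)
    if (!is.null(cand) && nrow(cand)) {
      key_old <- active_face_key(active)
      cand <- cand[!duplicated(active_face_key(cand)), , drop = FALSE]
      cand <- cand[!(active_face_key(cand) %in% key_old), , drop = FALSE]
      if (nrow(cand)) {
        cand$s_mm <- mesh$cells$s_mm[cand$cell]
        cand$branch <- mesh$cells$branch[cand$cell]
        add <- data.frame(cell = cand$cell, i = cand$i, j = cand$j,
                          side = cand$side, s_mm = cand$s_mm,
                          branch = cand$branch, segment = NA_integer_,
                          len = ifelse(cand$side %in% c("N", "S"),
                                       mesh$dx, mesh$dy),
                          stringsAsFactors = FALSE)
        active <- rbind(active[, names(add)], add)
        dep2 <- wall_deposition_state(nrow(add))
        dep$m_dp_cum <- c(dep$m_dp_cum, dep2$m_dp_cum)
        dep$rate <- c(dep$rate, dep2$rate)
        dep$phi <- c(dep$phi, dep2$phi)
        dep$q <- c(dep$q, dep2$q)
      }
    }
  }
  ## faces adjacent to clot cells no longer deposit (their cell is solid)
  drop <- resist$clot[active$cell]
  if (any(drop)) {
    active <- active[!drop, , drop = FALSE]
    dep$m_dp_cum <- dep$m_dp_cum[!drop]; dep$rate <- dep$rate[!drop]
    dep$phi <- dep$phi[!drop]; dep$q <- dep$q[!drop]
  }

  ## recompute with the updated clot set (newly marked cells keep fibrin)
  resist$inv_g_dp <- platelet_inverse_permeability(
    pmin(1, resist$phi_cell), params)
  scaffold <- resist$phi_cell >= params$phi_scaffold | resist$clot
  resist$inv_g_f <- numeric(n)
  if (!is.null(c_f) && any(scaffold))
    resist$inv_g_f[scaffold] <- fibrin_inverse_permeability(
      fibrin_fraction(c_f[scaffold], c_fg_ref), params$r_f)
  resist$inv_g_clot <- total_inverse_permeability(resist$inv_g_dp,
                                                  resist$inv_g_f)
  list(resist = resist, active = active, dep = dep, n_new = length(newly))
}
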