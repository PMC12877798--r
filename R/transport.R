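## Convection-diffusion-reaction transport of the nine species on the
## masked grid. One step = implicit Euler advection-diffusion solve per
## mobile species (first-order upwind fluxes from the staggered velocity
## field, central diffusion, inlet Dirichlet, outlet zero-diffusive-flux,
## species-specific fluxes on active deposition faces), followed by
## positivity-preserving semi-implicit (Patankar) reaction sub-steps.
## Fibrin is immobile (source only): polymerized fibrin does not convect.

#' Create a species concentration state over the mesh cells
#'
#' @param mesh a `clot_mesh`
#' @param c0 named initial concentrations (defaults to normal blood)
#' @return matrix `n_cells x 9` of class `species_state`
#' @export
species_state <- function(mesh, c0 = blood_concentrations()) {
  nm <- species_names()
  C <- matrix(rep(unlist(c0)[nm], each = mesh$n_cells),
              nrow = mesh$n_cells, dimnames = list(NULL, nm))
  class(C) <- c("species_state", class(C))
  C
}

## Precompute the transport stencil of a mesh: interior face pairs with
## their staggered-velocity positions, inlet and outlet face rows.
transport_stencil <- function(mesh) {
  nx <- mesh$nx; ny <- mesh$ny; fl <- mesh$fluid; cid <- mesh$cell_id
  ## x-faces between (i,j) and (i+1,j)
  bx <- which(fl[1:(nx - 1), , drop = FALSE] & fl[2:nx, , drop = FALSE],
              arr.ind = TRUE)
  xf <- list(a = cid[cbind(bx[, 1], bx[, 2])],
             b = cid[cbind(bx[, 1] + 1L, bx[, 2])],
             upos = lin_idx(bx[, 1] + 1L, bx[, 2], nx + 1L))
  by <- which(fl[, 1:(ny - 1), drop = FALSE] & fl[, 2:ny, drop = FALSE],
              arr.ind = TRUE)
  yf <- list(a = cid[cbind(by[, 1], by[, 2])],
             b = cid[cbind(by[, 1], by[, 2] + 1L)],
             vpos = lin_idx(by[, 1], by[, 2] + 1L, nx))
  f <- mesh$faces
  list(xf = xf, yf = yf,
       inlet = f[f$label == "inlet", , drop = FALSE],
       outlet = f[grepl("^outlet", f$label), , drop = FALSE])
}

#' Advance the species fields by one transport-reaction step
#'
#' @param C a `species_state` matrix (PLT/ml for platelets, uM for
#'   chemical species, U/ml for thrombin)
#' @param flow a `flow_field` on the same mesh
#' @param mesh the `clot_mesh`
#' @param dt time step, s
#' @param params [kinetic_parameters()]
#' @param active data.frame of active deposition faces (columns `cell`,
#'   `side`, `len`), or `NULL` for no surface reactions
#' @param dep the matching `wall_deposition_state` (for `phi`, `q`)
#' @param inlet named inlet concentrations
#' @param gamma_dot per-cell shear rate (1/s) for the shear-enhanced
#'   platelet diffusivity; scalar 0 gives the quiescent value
#' @param gamma_face optional per-face wall shear rate for the capture
#'   coefficients (see [face_capture_keff()])
#' @param kinetics_scale multiplier applied to every reaction and surface
#'   rate (time-scale compression for scaled runs)
#' @param stencil optional cached [transport_stencil()]
#' @param transport set `FALSE` to skip advection-diffusion (reaction only)
#' @return updated `species_state`
#' @export
advance_species <- function(C, flow, mesh, dt, params = kinetic_parameters(),
                            active = NULL, dep = NULL,
                            inlet = blood_concentrations(),
                            gamma_dot = 0, gamma_face = NULL,
                            kinetics_scale = 1,
                            stencil = NULL, transport = TRUE) {
  stopifnot(dt > 0)
  nm <- species_names()
  n <- mesh$n_cells
  ks <- kinetics_scale
  if (transport) {
    if (is.null(stencil)) stencil <- transport_stencil(mesh)
    dx <- mesh$dx; dy <- mesh$dy; vol <- dx * dy
    dplt <- platelet_diffusivity(rep_len(gamma_dot, n), params)
    diff_of <- list(rp = dplt, ap = dplt,
                    adp = params$d_adp, tx = params$d_tx,
                    pt = params$d_pt, t = params$d_t, at = params$d_at,
                    fg = params$d_fg)
    xf <- stencil$xf; yf <- stencil$yf
    Fx <- flow$u[xf$upos] * dy          # m2/s per unit depth
    Fy <- flow$v[yf$vpos] * dx
    ## upwind advection triplets (shared across species)
    adv <- list(
      i = c(xf$a, xf$b, xf$b, xf$a, yf$a, yf$b, yf$b, yf$a),
      j = c(xf$a, xf$a, xf$b, xf$b, yf$a, yf$a, yf$b, yf$b),
      x = c(pmax(Fx, 0), -pmax(Fx, 0), -pmin(Fx, 0), pmin(Fx, 0),
            pmax(Fy, 0), -pmax(Fy, 0), -pmin(Fy, 0), pmin(Fy, 0))
    )
    ## boundary advection: inlet inflow (RHS), outlet outflow (diagonal)
    inl <- stencil$inlet; outl <- stencil$outlet
    Fin <- flow$u[lin_idx(1L, inl$j, mesh$nx + 1L)] * dy      # >= 0 into domain
    Fout <- flow$u[lin_idx(rep(mesh$nx + 1L, nrow(outl)), outl$j,
                           mesh$nx + 1L)] * dy
    adv$i <- c(adv$i, outl$cell); adv$j <- c(adv$j, outl$cell)
    adv$x <- c(adv$x, pmax(Fout, 0))
    ## wall fluxes on active faces: removal coefficients (implicit) and
    ## release sources (explicit, lagged); platelet capture uses the
    ## boundary-layer-limited effective coefficients
    keff <- if (!is.null(active) && nrow(active))
      face_capture_keff(active, gamma_dot, mesh, params, gamma_face)
      else NULL
    act_coef <- function(spec) {
      out <- list(i = integer(0), x = numeric(0), rhs_i = integer(0),
                  rhs_x = numeric(0))
      if (is.null(active) || !nrow(active)) return(out)
      phi <- dep$phi; q <- dep$q; lenm <- active$len
      cw <- lapply(nm, function(s) C[active$cell, s])
      names(cw) <- nm
      if (spec %in% c("rp", "ap", "pt")) {
        ## linear removal j = coef * C -> implicit
        coef <- switch(spec,
          rp = q * keff$rpd,
          ap = q * keff$apd + phi * keff$apa,
          pt = params$beta * phi * params$k_ap_t) * ks
        out$i <- active$cell; out$x <- coef * lenm
        return(out)
      }
      j <- switch(spec,
        adp = -params$lambda_adp * q * keff$rpd * cw$rp,
        tx  = -phi * params$s_tx,
        t   = -phi * params$k_ap_t * cw$pt,
        NULL)
      if (is.null(j)) return(out)
      out$rhs_i <- active$cell; out$rhs_x <- -j * ks * lenm   # release > 0
      out
    }
    Cnew <- C
    for (spec in nm) {
      if (spec == "f") next                      # immobile: reaction only
      D <- diff_of[[spec]]
      Dv <- rep_len(D, n)
      dfx <- (Dv[xf$a] + Dv[xf$b]) / 2 * dy / dx
      dfy <- (Dv[yf$a] + Dv[yf$b]) / 2 * dx / dy
      trip_i <- c(adv$i, xf$a, xf$b, xf$a, xf$b, yf$a, yf$b, yf$a, yf$b)
      trip_j <- c(adv$j, xf$a, xf$b, xf$b, xf$a, yf$a, yf$b, yf$b, yf$a)
      trip_x <- c(adv$x, dfx, dfx, -dfx, -dfx, dfy, dfy, -dfy, -dfy)
      rhs <- vol / dt * C[, spec]
      ## inlet: advective inflow + diffusive Dirichlet at half cell
      cin <- inlet[[spec]]
      din <- 2 * rep_len(Dv, n)[inl$cell] * dy / dx
      trip_i <- c(trip_i, inl$cell); trip_j <- c(trip_j, inl$cell)
      trip_x <- c(trip_x, din)
      rhs[inl$cell] <- rhs[inl$cell] + (Fin + din) * cin
      ac <- act_coef(spec)
      if (length(ac$i)) {
        trip_i <- c(trip_i, ac$i); trip_j <- c(trip_j, ac$i)
        trip_x <- c(trip_x, ac$x)
      }
      if (length(ac$rhs_i))
        rhs[ac$rhs_i] <- rhs[ac$rhs_i] + ac$rhs_x
      trip_i <- c(trip_i, seq_len(n)); trip_j <- c(trip_j, seq_len(n))
      trip_x <- c(trip_x, rep(vol / dt, n))
      A <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                                dims = c(n, n))
      sol <- as.numeric(Matrix::solve(A, rhs))
      neg <- sol < 0
      if (any(sol < -1e-9 * max(abs(sol), 1e-300)))
        stop("negative concentration beyond clamping tolerance in species ", spec)
      sol[neg] <- 0
      Cnew[, spec] <- sol
    }
    C <- Cnew
  }
  react_species(C, dt, params, kinetics_scale = ks)
}

#' Positivity-preserving reaction sub-stepping over all cells
#'
#' Semi-implicit (Patankar-type) update: each species' sink is treated
#' implicitly through its loss-rate coefficient, sources explicitly, so
#' concentrations stay non-negative for any step size. Sub-steps are
#' chosen so the fastest local loss rate is resolved.
#'
#' @param C a `species_state`
#' @param dt total reaction time, s
#' @param params [kinetic_parameters()]
#' @param kinetics_scale rate multiplier
#' @param max_substeps cap on the number of sub-steps
#' @return updated `species_state`
#' @export
react_species <- function(C, dt, params = kinetic_parameters(),
                          kinetics_scale = 1, max_substeps = 400L) {
  p <- params; ks <- kinetics_scale
  if (ks <= 0) return(C)
  ## estimate the stiffest loss rate to pick the sub-step
  act0 <- activation_rate(C[, "adp"], C[, "tx"], C[, "t"], p)
  gam0 <- thrombin_inactivation(C[, "t"], C[, "at"], p)
  lmax <- ks * max(act0$k_rpa, gam0, p$k_adp, p$k_tx, 1e-12)
  nsub <- min(max_substeps, max(1L, ceiling(dt * lmax / 0.2)))
  h <- dt / nsub
  for (s in seq_len(nsub)) {
    act <- activation_rate(C[, "adp"], C[, "tx"], C[, "t"], p)
    gam <- thrombin_inactivation(C[, "t"], C[, "at"], p)
    k_rpa <- ks * act$k_rpa
    gam <- ks * gam
    t_gen <- ks * C[, "pt"] * (p$k_ap_t * C[, "ap"] + p$k_rp_t * C[, "rp"])
    mm <- ks * p$k_fg_vmax * C[, "t"] / (p$k_fg_km + C[, "fg"])
    at_loss <- ifelse(C[, "at"] > 0, gam * p$beta * C[, "t"] / C[, "at"], 0)
    rp0 <- C[, "rp"]
    C[, "rp"] <- C[, "rp"] / (1 + h * k_rpa)
    C[, "ap"] <- C[, "ap"] + h * k_rpa * rp0 / (1 + h * k_rpa)
    C[, "adp"] <- (C[, "adp"] + h * p$lambda_adp * k_rpa * rp0 / (1 + h * k_rpa)) /
      (1 + h * ks * p$k_adp)
    C[, "tx"] <- (C[, "tx"] + h * ks * p$s_tx * C[, "ap"]) / (1 + h * ks * p$k_tx)
    pt_loss <- ks * p$beta * (p$k_ap_t * C[, "ap"] + p$k_rp_t * C[, "rp"])
    C[, "pt"] <- C[, "pt"] / (1 + h * pt_loss)
    C[, "t"] <- (C[, "t"] + h * t_gen) / (1 + h * gam)
    C[, "at"] <- C[, "at"] / (1 + h * at_loss)
    fg0 <- C[, "fg"]
    C[, "fg"] <- C[, "fg"] / (1 + h * mm)
    C[, "f"] <- C[, "f"] + h * mm * fg0 / (1 + h * mm)
  }
  C
}

#' Effective platelet capture coefficients for a set of wall faces
#'
#' Applies [wall_capture_keff()] with the local shear-dependent platelet
#' diffusivity at each active face's wall cell and the wall-normal
#' half-cell size of the face orientation.
#'
#' @param active active-face data.frame (columns `cell`, `side`)
#' @param gamma_dot per-cell shear rate, 1/s (scalar or vector)
#' @param mesh the `clot_mesh`
#' @param params [kinetic_parameters()]
#' @param gamma_face optional per-face wall shear rate (1/s) taking
#'   precedence over the cell values (the wall-profile estimate from
#'   [wall_shear()] where available)
#' @return list of per-face vectors `rpd`, `apd`, `apa` (m/s)
#' @export
face_capture_keff <- function(active, gamma_dot, mesh,
                              params = kinetic_parameters(),
                              gamma_face = NULL) {
  g <- rep_len(gamma_dot, mesh$n_cells)[active$cell]
  if (!is.null(gamma_face)) {
    ok <- !is.na(gamma_face)
    g[ok] <- gamma_face[ok]
  }
  dw <- platelet_diffusivity(g, params)
  hh <- ifelse(active$side %in% c("N", "S"), mesh$dy, mesh$dx) / 2
  list(rpd = wall_capture_keff(params$k_rpd, dw, hh),
       apd = wall_capture_keff(params$k_apd, dw, hh),
       apa = wall_capture_keff(params$k_apa, dw, hh))
}

#' Approximate per-cell shear rate of a flow field
#'
#' Magnitude of the dominant velocity-gradient components
#' `|du/dy| + |dv/dx|`, one-sided against the no-slip wall where a
#' neighbor is solid. Used for the shear-enhanced platelet diffusivity.
#'
#' @param flow a `flow_field`
#' @param mesh the `clot_mesh`
#' @return numeric vector over fluid cells, 1/s
#' @export
cell_shear_rate <- function(flow, mesh) {
  nx <- mesh$nx; ny <- mesh$ny; fl <- mesh$fluid
  uc <- flow$uc; vc <- flow$vc
  ci <- mesh$cells$i; cj <- mesh$cells$j
  gv <- function(M, ii, jj) {
    ok <- ii >= 1L & ii <= nx & jj >= 1L & jj <= ny
    v <- numeric(length(ii)); have <- logical(length(ii))
    li <- lin_idx(ii[ok], jj[ok], nx)
    v[ok] <- M[li]; have[ok] <- fl[li]
    list(v = v, ok = have)
  }
  grad1 <- function(M, di, dj, h) {
    P <- M[lin_idx(ci, cj, nx)]
    up <- gv(M, ci + di, cj + dj); dn <- gv(M, ci - di, cj - dj)
    g <- numeric(length(ci))
    both <- up$ok & dn$ok
    g[both] <- (up$v[both] - dn$v[both]) / (2 * h)
    onlyu <- up$ok & !dn$ok   # wall on the minus side at half a cell
    g[onlyu] <- P[onlyu] / (h / 2)
    onlyd <- dn$ok & !up$ok
    g[onlyd] <- P[onlyd] / (h / 2)
    none <- !up$ok & !dn$ok
    g[none] <- P[none] / (h / 2)
    abs(g)
  }
  grad1(uc, 0L, 1L, mesh$dy) + grad1(vc, 1L, 0L, mesh$dx)
}
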