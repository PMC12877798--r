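## Nine-species coagulation kinetics: platelet activation, agonist
## release, thrombin generation/inhibition, fibrin formation, wall
## deposition fluxes.
##
## Species order (see species_names()): rp, ap (PLT/ml), adp, tx, pt, at,
## fg, f (uM), t (U/ml). With these units nmol/ml == uM, so all Table-style
## rate constants combine without conversion factors; beta converts U/ml
## to uM where thrombin enters a molar balance.

#' Platelet activation state from the agonist index
#'
#' The activation index is the sum of agonist concentrations relative to
#' their critical values, `Omega = C_ADP/C_ADP_cri + C_TX/C_TX_cri +
#' C_T/C_T_cri`. Resting platelets activate at rate `Omega/t_act` once
#' `Omega` exceeds 1 (the boundary `Omega = 1` is inactive).
#'
#' @param c_adp,c_tx ADP and thromboxane concentrations, uM
#' @param c_t thrombin, U/ml
#' @param params [kinetic_parameters()]
#' @return list with `omega` and the activation rate `k_rpa` (1/s), both
#'   vectorized over the inputs
#' @export
#' @examples
#' activation_rate(4, 0, 0)$k_rpa  # Omega = 2 -> 2 s^-1
activation_rate <- function(c_adp, c_tx, c_t, params = kinetic_parameters()) {
  omega <- c_adp / params$c_adp_cri + c_tx / params$c_tx_cri + c_t / params$c_t_cri
  k_rpa <- ifelse(omega > 1, omega / params$t_act, 0)
  list(omega = omega, k_rpa = k_rpa)
}

#' Heparin-catalyzed thrombin inactivation rate (Griffith template model)
#'
#' `Gamma = k_T C_H C_AT / (alpha (C_ATd C_Td + C_AT C_Td + C_ATd C_T +
#' C_AT C_T))` with thrombin converted from U/ml to uM via `beta` before
#' evaluation.
#'
#' @param c_t thrombin, U/ml
#' @param c_at antithrombin, uM
#' @param params [kinetic_parameters()]
#' @return inactivation rate Gamma, 1/s (vectorized)
#' @export
thrombin_inactivation <- function(c_t, c_at, params = kinetic_parameters()) {
  ct_um <- params$beta * c_t
  den <- params$alpha * (params$c_at_dis * params$c_t_dis +
                         c_at * params$c_t_dis +
                         params$c_at_dis * ct_um +
                         c_at * ct_um)
  params$k_t * params$c_h * c_at / den
}

#' Shear-dependent platelet diffusivity
#'
#' Shear-enhanced effective diffusivity of (resting and activated)
#' platelets, `D = (13.61 gamma_dot + 1.58) x 1e-13` m2/s.
#'
#' @param gamma_dot shear rate, 1/s
#' @param params [kinetic_parameters()]
#' @return diffusivity, m2/s (vectorized)
#' @export
platelet_diffusivity <- function(gamma_dot, params = kinetic_parameters()) {
  params$d_plt_slope * gamma_dot + params$d_plt_intercept
}

#' Volumetric reaction source terms for the nine species
#'
#' @param conc named list/matrix of concentrations: vectors `rp`, `ap`
#'   (PLT/ml), `adp`, `tx`, `pt`, `at`, `fg`, `f` (uM), `t` (U/ml)
#' @param k_rpa platelet activation rate, 1/s
#' @param gamma_inact thrombin inactivation rate Gamma, 1/s (computed via
#'   [thrombin_inactivation()] if `NULL`)
#' @param params [kinetic_parameters()]
#' @return named list of per-species sources in concentration units per s
#' @export
reaction_sources <- function(conc, k_rpa = NULL, gamma_inact = NULL,
                             params = kinetic_parameters()) {
  p <- params
  if (is.null(k_rpa))
    k_rpa <- activation_rate(conc$adp, conc$tx, conc$t, p)$k_rpa
  if (is.null(gamma_inact))
    gamma_inact <- thrombin_inactivation(conc$t, conc$at, p)
  t_gen <- conc$pt * (p$k_ap_t * conc$ap + p$k_rp_t * conc$rp)  # U/(ml s)
  s_f <- p$k_fg_vmax * conc$t * conc$fg / (p$k_fg_km + conc$fg)
  list(
    rp  = -k_rpa * conc$rp,
    ap  = +k_rpa * conc$rp,
    adp = p$lambda_adp * k_rpa * conc$rp - p$k_adp * conc$adp,
    tx  = p$s_tx * conc$ap - p$k_tx * conc$tx,
    pt  = -p$beta * t_gen,
    t   = -gamma_inact * conc$t + t_gen,
    at  = -gamma_inact * p$beta * conc$t,
    fg  = -s_f,
    f   = +s_f
  )
}

#' Species boundary fluxes on the thrombogenic wall
#'
#' Fluxes in the species' own concentration unit times m/s; positive
#' values remove the species from the fluid (platelet deposition), and
#' negative values release it (ADP from lysing granules, thromboxane from
#' the covered surface, thrombin generated at the plug).
#'
#' @param conc named list of near-wall concentrations (as in
#'   [reaction_sources()])
#' @param phi surface coverage fraction
#' @param q free surface fraction `1 - phi`
#' @param params [kinetic_parameters()]
#' @return named list of per-species wall fluxes (species without a
#'   surface reaction are absent = zero flux)
#' @export
wall_species_fluxes <- function(conc, phi, q = 1 - phi,
                                params = kinetic_parameters()) {
  p <- params
  list(
    rp  = q * p$k_rpd * conc$rp,
    ap  = (q * p$k_apd + phi * p$k_apa) * conc$ap,
    adp = -p$lambda_adp * q * p$k_rpd * conc$rp,
    tx  = -phi * p$s_tx,
    pt  = p$beta * phi * p$k_ap_t * conc$pt,
    t   = -phi * p$k_ap_t * conc$pt
  )
}

#' Platelet deposition rate onto an active surface
#'
#' `M_DP = q K_RPD C_RP + q K_APD C_AP + K_APA C_AP phi` converted to
#' PLT/m2/s (concentrations are PLT/ml).
#'
#' @inheritParams wall_species_fluxes
#' @param k_eff optional list of effective capture coefficients `rpd`,
#'   `apd`, `apa` (m/s, possibly per-face vectors) replacing the kinetic
#'   constants; see [wall_capture_keff()]
#' @return deposition rate, PLT/(m2 s)
#' @export
deposition_rate <- function(conc, phi, q = 1 - phi,
                            params = kinetic_parameters(), k_eff = NULL) {
  p <- params
  if (is.null(k_eff))
    k_eff <- list(rpd = p$k_rpd, apd = p$k_apd, apa = p$k_apa)
  1e6 * (q * k_eff$rpd * conc$rp + q * k_eff$apd * conc$ap +
           k_eff$apa * conc$ap * phi)
}

#' Boundary-layer-limited effective wall capture coefficient
#'
#' On a coarse grid the near-wall concentration boundary layer of the
#' platelet capture reaction is thinner than a cell, so the kinetic
#' coefficient `K` is combined in series with the diffusive conductance
#' of the half cell adjacent to the wall, evaluated with the local
#' shear-dependent platelet diffusivity:
#' `1/K_eff = 1/K + (h/2)/D(gamma_dot)`. `K_eff -> K` under grid
#' refinement; the shear dependence of `D` is what concentrates
#' deposition near the stenosis apex.
#'
#' @param K kinetic capture coefficient, m/s
#' @param d_wall near-wall diffusivity, m2/s
#' @param h_half wall-normal half-cell size, m
#' @return effective coefficient, m/s (vectorized)
#' @export
wall_capture_keff <- function(K, d_wall, h_half) {
  1 / (1 / K + h_half / d_wall)
}

#' Create the wall deposition state for a set of active faces
#'
#' @param n_faces number of active deposition faces
#' @return list of class `wall_deposition_state` with cumulative deposit
#'   `m_dp_cum` (PLT/m2), instantaneous rate, coverage `phi` and free
#'   fraction `q`
#' @export
wall_deposition_state <- function(n_faces) {
  structure(list(
    m_dp_cum = numeric(n_faces), rate = numeric(n_faces),
    phi = numeric(n_faces), q = rep(1, n_faces)
  ), class = "wall_deposition_state")
}

#' Advance the wall deposition state by one time step
#'
#' Integrates the deposition rate, clamps the coverage to `[0, 1]` at the
#' saturation density `M_max` and keeps `q = 1 - phi`.
#'
#' @param state a `wall_deposition_state`
#' @param conc named list of near-wall concentration vectors over the
#'   active faces
#' @param dt time step, s
#' @param params [kinetic_parameters()]
#' @param rate_scale optional multiplier on the deposition rate (kinetics
#'   time-scale factor)
#' @param k_eff optional effective capture coefficients (see
#'   [deposition_rate()])
#' @return updated state
#' @export
update_deposition <- function(state, conc, dt, params = kinetic_parameters(),
                              rate_scale = 1, k_eff = NULL) {
  stopifnot(dt > 0)
  rate <- deposition_rate(conc, state$phi, state$q, params, k_eff) * rate_scale
  state$rate <- rate
  state$m_dp_cum <- state$m_dp_cum + rate * dt
  state$phi <- pmin(1, state$m_dp_cum / params$m_max)
  state$q <- 1 - state$phi
  state
}

## ---- well-mixed (0-D) reactor -------------------------------------------

rhs_wellmixed <- function(y, params) {
  conc <- as.list(y)
  unlist(reaction_sources(conc, params = params), use.names = TRUE)
}

#' Integrate the reaction network in a closed well-mixed volume
#'
#' Adaptive embedded Runge-Kutta (Cash-Karp 4/5) integration of the
#' nine-species source system (no transport, no walls). The step size
#' tracks the locally fastest rate (e.g. thrombin inactivation at normal
#' antithrombin, ~1e2 1/s, or terminal fibrinogen depletion), so slow
#' platelet activation and fast inhibition are both resolved.
#'
#' @param c0 named initial concentrations (see [blood_concentrations()])
#' @param t_end final time, s
#' @param params [kinetic_parameters()]
#' @param times output times (defaults to 101 uniform points)
#' @param rtol,atol_rel relative tolerance and the absolute tolerance
#'   expressed relative to each species' initial scale
#' @return data.frame: `time` plus one column per species
#' @export
simulate_wellmixed <- function(c0 = blood_concentrations(), t_end = 10,
                               params = kinetic_parameters(),
                               times = NULL, rtol = 1e-8, atol_rel = 1e-14) {
  nm <- species_names()
  y <- unlist(c0)[nm]
  if (is.null(times)) times <- seq(0, t_end, length.out = 101)
  times <- sort(unique(c(0, times)))
  scale0 <- pmax(abs(y), c(rp = 1e8, ap = 1e6, adp = 1, tx = 0.1, pt = 1,
                           t = 0.1, at = 1, fg = 1, f = 1)[nm] * 1e-6)
  atol <- atol_rel * scale0
  ## Cash-Karp tableau
  a <- list(c(1/5),
            c(3/40, 9/40),
            c(3/10, -9/10, 6/5),
            c(-11/54, 5/2, -70/27, 35/27),
            c(1631/55296, 175/512, 575/13824, 44275/110592, 253/4096))
  b5 <- c(37/378, 0, 250/621, 125/594, 0, 512/1771)
  b4 <- c(2825/27648, 0, 18575/48384, 13525/55296, 277/14336, 1/4)
  out <- matrix(NA_real_, length(times), length(nm) + 1,
                dimnames = list(NULL, c("time", nm)))
  out[1, ] <- c(0, y)
  t <- 0; h <- min(1e-3, t_end / 10)
  for (ti in seq_along(times)[-1]) {
    tgt <- times[ti]
    while (t < tgt - 1e-15 * max(1, tgt)) {
      h <- min(h, tgt - t)
      k1 <- rhs_wellmixed(y, params)
      k2 <- rhs_wellmixed(y + h * a[[1]][1] * k1, params)
      k3 <- rhs_wellmixed(y + h * (a[[2]][1] * k1 + a[[2]][2] * k2), params)
      k4 <- rhs_wellmixed(y + h * (a[[3]][1] * k1 + a[[3]][2] * k2 +
                                     a[[3]][3] * k3), params)
      k5 <- rhs_wellmixed(y + h * (a[[4]][1] * k1 + a[[4]][2] * k2 +
                                     a[[4]][3] * k3 + a[[4]][4] * k4), params)
      k6 <- rhs_wellmixed(y + h * (a[[5]][1] * k1 + a[[5]][2] * k2 +
                                     a[[5]][3] * k3 + a[[5]][4] * k4 +
                                     a[[5]][5] * k5), params)
      y5 <- y + h * (b5[1] * k1 + b5[3] * k3 + b5[4] * k4 + b5[6] * k6)
      y4 <- y + h * (b4[1] * k1 + b4[3] * k3 + b4[4] * k4 + b4[5] * k5 +
                       b4[6] * k6)
      err <- max(abs(y5 - y4) / (atol + rtol * pmax(abs(y), abs(y5))))
      if (is.finite(err) && err <= 1) {
        t <- t + h
        y <- pmax(y5, 0)
        h <- h * min(5, max(0.2, 0.9 * err^(-0.2)))
      } else {
        h <- h * max(0.1, 0.9 * if (is.finite(err)) err^(-0.25) else 0.1)
        if (h < 1e-14) stop("step size underflow in well-mixed integration")
      }
    }
    out[ti, ] <- c(t, y)
  }
  as.data.frame(out)
}
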