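p <- kinetic_parameters()

test_that("platelet activation follows the agonist index with a strict threshold", {
  a0 <- activation_rate(0, 0, 0, p)
  expect_equal(a0$omega, 0); expect_equal(a0$k_rpa, 0)
  a1 <- activation_rate(4, 0, 0, p)      # omega = 4/2 = 2
  expect_equal(a1$omega, 2)
  expect_equal(a1$k_rpa, 2 / p$t_act)
  ## the boundary omega = 1 stays inactive
  ab <- activation_rate(2, 0, 0, p)
  expect_equal(ab$omega, 1); expect_equal(ab$k_rpa, 0)
  ## all three agonists contribute
  am <- activation_rate(1, 0.3, 0.05, p)
  expect_equal(am$omega, 0.5 + 0.5 + 0.5)
})

test_that("Griffith thrombin inactivation matches direct evaluation", {
  expect_equal(thrombin_inactivation(0, 0, p), 0)
  ## reference point evaluated in uM: C_AT = 0.1, C_T = 0.035 uM
  g <- thrombin_inactivation(0.035 / p$beta, 0.1, p)
  expect_equal(g, 13.333 * 0.3 * 0.1 / 0.014, tolerance = 1e-12)
  expect_equal(g, 28.57, tolerance = 1e-3)
  ## Gamma -> 0 as thrombin grows without bound
  gs <- thrombin_inactivation(c(1, 1e3, 1e6), 1, p)
  expect_true(all(diff(gs) < 0))
  expect_lt(gs[3], 1e-3)
})

test_that("platelet diffusivity is the shear-linear Keller law", {
  expect_equal(platelet_diffusivity(0), 1.58e-13)
  expect_equal(platelet_diffusivity(100), 1.36258e-10, tolerance = 1e-12)
  g <- seq(0, 5000, by = 100)
  expect_true(all(diff(platelet_diffusivity(g)) > 0))
})

test_that("the nine source terms agree with an independent oracle on 1000 states", {
  set.seed(7)
  worst <- 0
  for (k in 1:1000) {
    cc <- random_state()
    s <- unlist(reaction_sources(cc, params = p))
    o <- oracle_sources(cc, p)
    worst <- max(worst, abs(s[names(o)] - o) / pmax(abs(o), 1e-30))
  }
  expect_lt(worst, 1e-12)
})

test_that("fibrinogen and fibrin sources cancel exactly", {
  set.seed(8)
  for (k in 1:50) {
    cc <- random_state()
    s <- reaction_sources(cc, params = p)
    expect_identical(s$fg + s$f, 0)
  }
})

test_that("a pure resting-platelet state activates into the expected sources", {
  cc <- list(rp = 1e14, ap = 0, adp = 0, tx = 0, pt = 0, t = 0, at = 0,
             fg = 0, f = 0)
  s <- reaction_sources(cc, k_rpa = 1, gamma_inact = 0, params = p)
  expect_equal(s$rp, -1e14)
  expect_equal(s$ap, +1e14)
  expect_equal(s$adp, p$lambda_adp * 1e14)
  expect_equal(s$tx, 0); expect_equal(s$pt, 0); expect_equal(s$t, 0)
  expect_equal(s$at, 0); expect_equal(s$fg, 0); expect_equal(s$f, 0)
})

test_that("thrombogenic-wall fluxes follow the boundary table", {
  cc <- list(rp = 0, ap = 1e6, adp = 0, tx = 0, pt = 0, t = 0, at = 0,
             fg = 0, f = 0)
  j <- wall_species_fluxes(cc, phi = 0, params = p)
  expect_equal(j$ap, p$k_apd * 1e6)            # fresh collagen, q = 1
  cc0 <- lapply(cc, function(x) 0)
  j2 <- wall_species_fluxes(cc0, phi = 0.5, params = p)
  expect_equal(j2$tx, -0.5 * p$s_tx)           # covered surface releases TX
  expect_true(all(unlist(j2[setdiff(names(j2), "tx")]) == 0))
  j3 <- wall_species_fluxes(cc0, phi = 0, params = p)
  expect_true(all(unlist(j3) == 0))
})

test_that("deposition integrates the surface coverage with saturation", {
  st <- wall_deposition_state(3)
  cc0 <- list(rp = rep(0, 3), ap = rep(0, 3), adp = 0, tx = 0, pt = 0,
              t = 0, at = 0, fg = 0, f = 0)
  st2 <- update_deposition(st, cc0, dt = 1, p)
  expect_equal(st2$phi, rep(0, 3))
  expect_equal(st2$q, rep(1, 3))
  ## constant resting-platelet exposure: phi = r t / M_max up to the clamp
  cc <- list(rp = rep(2.5e8, 3), ap = rep(0, 3), adp = 0, tx = 0, pt = 0,
             t = 0, at = 0, fg = 0, f = 0)
  r0 <- 1e6 * p$k_rpd * 2.5e8            # q = 1 initial rate
  st3 <- wall_deposition_state(3)
  dt <- 1e-3
  for (s in 1:100) st3 <- update_deposition(st3, cc, dt, p)
  ## forward-Euler of dphi/dt = r0 (1 - phi) / M_max over 0.1 s
  phi_exact <- 1 - (1 - r0 * dt / p$m_max)^100
  expect_equal(st3$phi[1], phi_exact, tolerance = 1e-6)
  ## saturation clamps at full coverage
  st4 <- wall_deposition_state(1)
  ccb <- list(rp = 1e12, ap = 1e10, adp = 0, tx = 0, pt = 0, t = 0,
              at = 0, fg = 0, f = 0)
  for (s in 1:200) st4 <- update_deposition(st4, ccb, 1, p)
  expect_equal(st4$phi, 1)
  expect_equal(st4$q, 0)
  expect_equal(wall_species_fluxes(ccb, phi = 1, params = p)$rp, 0)
  ## cumulative deposit never decreases
  expect_true(st4$m_dp_cum >= st3$m_dp_cum[1])
})

test_that("boundary-layer limitation reduces capture and vanishes on refinement", {
  k <- wall_capture_keff(p$k_rpd, platelet_diffusivity(300), 1e-4)
  expect_lt(k, p$k_rpd)
  k_fine <- wall_capture_keff(p$k_rpd, platelet_diffusivity(300), 1e-7)
  expect_equal(k_fine, p$k_rpd, tolerance = 0.01)
})

test_that("well-mixed integration matches an independent stiff reference", {
  skip_if_not_installed("deSolve")
  c0 <- blood_concentrations()
  c0["adp"] <- 4                         # triggers activation
  f <- function(t, y, parms) list(clotflow:::rhs_wellmixed(y, p))
  ref <- deSolve::ode(unlist(c0)[species_names()], c(0, 10), f, NULL,
                      method = "lsoda", rtol = 1e-11, atol = 1e-14)
  mine <- simulate_wellmixed(c0, 10, p)
  a <- as.numeric(ref[2, -1]); b <- as.numeric(mine[nrow(mine), -1])
  scale0 <- pmax(abs(unlist(c0)[species_names()]), 1e-3)
  rel <- abs(a - b) / pmax(abs(a), 1e-10 * scale0)
  expect_lt(max(rel), 1e-3)
})

test_that("closed-system invariants hold in the well-mixed reactor", {
  c0 <- blood_concentrations(); c0["adp"] <- 4
  ## FG + F conserved
  m <- simulate_wellmixed(c0, 5, p)
  tot <- m$fg + m$f
  expect_lt(diff(range(tot)) / tot[1], 1e-8)
  ## PT + beta T conserved when Gamma = 0 (no heparin)
  p0 <- kinetic_parameters(c_h = 0)
  m0 <- simulate_wellmixed(c0, 5, p0)
  tot2 <- m0$pt + p$beta * m0$t
  expect_lt(diff(range(tot2)) / tot2[1], 1e-6)
  ## RP + AP conserved; AT non-increasing under active Gamma
  totp <- m$rp + m$ap
  expect_lt(diff(range(totp)) / totp[1], 1e-8)
  expect_true(all(diff(m$at) <= 1e-12))
  ## positivity throughout
  expect_true(all(as.matrix(m[, -1]) >= 0))
})
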