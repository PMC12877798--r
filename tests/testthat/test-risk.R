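test_that("thrombogenic area selects in-band faces above threshold only", {
  g <- build_stenosed_tube(2, stenosis_spec(0.35, 4))
  m <- generate_mesh(g, 0.1)
  w <- m$faces[m$faces$label == "wall", ]
  prof <- data.frame(face_id = w$id, arclength_mm = w$s_mm,
                     tau_pa = 5, in_band = w$in_band)
  expect_equal(nrow(thrombogenic_area(prof, 7)$faces), 0)
  prof$tau_pa <- 10
  ta <- thrombogenic_area(prof, 7)
  expect_equal(sort(ta$face_ids), sort(w$id[w$in_band]))
  ## out-of-band faces stay excluded even at high shear
  expect_true(all(ta$faces$in_band))
  ## mixed profile crossing the threshold inside the band
  prof$tau_pa <- ifelse(prof$arclength_mm > 5 & prof$arclength_mm < 7, 12, 3)
  ta2 <- thrombogenic_area(prof, 7)
  expect_true(all(ta2$faces$arclength_mm > 5 & ta2$faces$arclength_mm < 7))
  ## raising the threshold never enlarges the set
  n_thr <- vapply(c(2, 5, 8, 11, 13),
                  function(th) nrow(thrombogenic_area(prof, th)$faces),
                  numeric(1))
  expect_true(all(diff(n_thr) <= 0))
})

test_that("power-law shear model evaluates the separable form", {
  m <- shear_risk_model()
  expect_equal(m$e, 6.408)
  expect_equal(m$f, -3.56)
  ## reported-coefficient evaluation at the patient-1-style inputs
  v <- tau_max_powerlaw(2, 4.1, 3.5, 0.63, m)
  ref <- 4.99 * 2^1.35 * 4.1^5.02 * 3.5^-0.45 * (0.63^1.80 / (1 - 0.63))^3.56
  expect_equal(v, ref, tolerance = 1e-12)
  expect_equal(v, 1.539e4, tolerance = 1e-3)
  ## vanishes as the stenosis disappears; increases with the degree
  expect_lt(tau_max_powerlaw(2, 4.1, 3.5, 1e-8, m), 1e-6)
  eps <- seq(0.1, 0.9, by = 0.1)
  expect_true(all(diff(tau_max_powerlaw(2, 4.1, 3.5, eps, m)) > 0))
  expect_error(tau_max_powerlaw(2, 4.1, 3.5, 1, m), "degree")
})

test_that("log-linear fitting recovers exact coefficients and resists noise", {
  set.seed(123)
  truth <- shear_risk_model(a = 3.1, b = 1.2, c = 4.5, d = -0.6,
                            e = 5.5, f = -3.1)
  n <- 200
  rec <- data.frame(vdot = runif(n, 0.5, 4), d_lmca = runif(n, 3, 6),
                    d_ste = runif(n, 2, 4.5), eps = runif(n, 0.2, 0.85))
  rec$tau_max <- tau_max_powerlaw(rec$vdot, rec$d_lmca, rec$d_ste,
                                  rec$eps, truth)
  fit <- fit_powerlaw(rec)
  for (cf in c("a", "b", "c", "d", "e", "f"))
    expect_equal(fit[[cf]], truth[[cf]], tolerance = 1e-8)
  ## 1% multiplicative lognormal noise: exponents within 5%
  rec$tau_max <- rec$tau_max * exp(rnorm(n, 0, 0.01))
  fit2 <- fit_powerlaw(rec)
  for (cf in c("b", "c", "d", "e", "f"))
    expect_lt(abs(fit2[[cf]] - truth[[cf]]) / abs(truth[[cf]]), 0.05)
  ## under-determined and degenerate designs are rejected
  expect_error(fit_powerlaw(rec[1:5, ]), "6")
  bad <- rec[1:20, ]; bad$d_lmca <- 4
  bad$d_ste <- 4
  expect_error(fit_powerlaw(bad), "collinear")
})

test_that("risk classification is a strict 7 Pa rule", {
  r <- classify_risk(c(6, 7, 8))
  expect_equal(as.character(r), c("low_risk", "low_risk", "high_risk"))
  expect_error(classify_risk(-1))
})

test_that("equivalent-vessel shear reproduces circular Poiseuille in a tube", {
  g <- build_stenosed_tube(2, stenosis_spec(0, 4))
  m <- generate_mesh(g, 0.1)
  Q <- 10 / 6e7
  fl <- solve_flow(m, NULL, boundary_conditions(Q))
  ws <- equivalent_tube_shear(wall_shear(fl, m), fl, m, Q)
  tau_ref <- 32 * 0.0035 * Q / (pi * (2e-3)^3)
  expect_equal(unique(round(ws$tau_eq_pa, 10)), round(tau_ref, 10))
})

test_that("simulated peak shear rises with stenosis degree and falls with diameter", {
  grid <- expand.grid(vdot = 2e-6, d_lmca = 4.1, d_ste = c(3.0, 3.6),
                      d_other = 3.0, eps = c(0.35, 0.5, 0.65))
  sw <- simulate_shear_sweep(grid, length_factor = 3, tol = 5e-4)
  for (d in unique(sw$d_ste)) {
    sub <- sw[sw$d_ste == d, ]
    expect_true(all(diff(sub$tau_max[order(sub$eps)]) > 0))
  }
  for (e in unique(sw$eps)) {
    sub <- sw[sw$eps == e, ]
    expect_gt(sub$tau_max[sub$d_ste == 3.0], sub$tau_max[sub$d_ste == 3.6])
  }
})
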