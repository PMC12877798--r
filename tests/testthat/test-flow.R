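props <- fluid_properties()

test_that("plane Poiseuille flow reproduces the closed-form wall shear", {
  s <- poiseuille_setup(H_mm = 2, n_across = 20)
  bc <- boundary_conditions(flow_rate = 10 / 6e7)
  fl <- solve_flow(s$mesh, NULL, bc, props)
  H <- 2e-3
  tau_exact <- 6 * props$viscosity * fl$qbar / H^2
  ws <- wall_shear(fl, s$mesh, props)
  mid <- ws[ws$arclength_mm > 3 & ws$arclength_mm < 13, ]
  expect_lt(max(abs(mid$tau_pa - tau_exact)) / tau_exact, 0.02)
  ## gamma_dot = tau/mu identically
  expect_equal(ws$gamma_dot, ws$tau_pa / props$viscosity)
  ## velocity vanishes on the boundary rows through the no-slip ghosts
  expect_lt(fl$div_residual, 1e-8)
})

test_that("uniform inverse permeability reproduces the Darcy limit", {
  s <- poiseuille_setup(H_mm = 2, n_across = 20)
  bc <- boundary_conditions(flow_rate = 1e-8)
  invg <- rep(1e12, s$mesh$n_cells)
  fl <- solve_flow(s$mesh, invg, bc, props, advection = FALSE)
  ## mean velocity = G dp / (mu L) between two axial stations
  i1 <- 2L; i2 <- s$mesh$nx - 1L
  p1 <- mean(fl$p[i1, ], na.rm = TRUE); p2 <- mean(fl$p[i2, ], na.rm = TRUE)
  L <- (i2 - i1) * s$mesh$dx
  u_mean <- fl$qbar / 2e-3
  pred <- 1e-12 * (p1 - p2) / (props$viscosity * L)
  expect_lt(abs(u_mean - pred) / pred, 0.02)
})

test_that("negative inverse permeability is rejected", {
  s <- poiseuille_setup()
  expect_error(solve_flow(s$mesh, rep(-1, s$mesh$n_cells),
                          boundary_conditions(1e-8), props), "negative")
})

test_that("a mirror-symmetric clot-free bifurcation splits the flow 50/50", {
  pt <- patient_table()
  p <- pt[1, ]; p$stenosis_degree <- 0; p$d_lad <- 3; p$d_lcx <- 3
  g <- build_bifurcation(p, length_factor = 3)
  m <- generate_mesh(g, 0.3)
  fl <- solve_flow(m, NULL, boundary_conditions(2e-6), props)
  br <- branch_flow_rates(fl, m)
  expect_lt(abs(br$fractions[["outlet_1"]] - 0.5), 0.01)
  expect_lt(abs(br$balance), 0.005)
})

test_that("global mass balance holds for stenosed-tube and bifurcation solves", {
  g <- build_stenosed_tube(2, stenosis_spec(0.35, 4))
  m <- generate_mesh(g, 0.1)
  fl <- solve_flow(m, NULL, boundary_conditions(10 / 6e7), props)
  expect_lt(abs(branch_flow_rates(fl, m)$balance), 0.005)
  pt <- patient_table()
  g2 <- build_bifurcation(pt[6, ], length_factor = 3)
  m2 <- generate_mesh(g2, 0.23)
  fl2 <- solve_flow(m2, NULL, boundary_conditions(2e-6), props)
  expect_lt(abs(branch_flow_rates(fl2, m2)$balance), 0.005)
})

test_that("zero inlet flow gives zero wall shear everywhere", {
  s <- poiseuille_setup(n_across = 10)
  fl <- solve_flow(s$mesh, NULL, boundary_conditions(0), props,
                   advection = FALSE)
  ws <- wall_shear(fl, s$mesh, props)
  expect_true(all(ws$tau_pa < 1e-12))
})

test_that("blocking one branch with capped resistance starves it", {
  pt <- patient_table()
  p <- pt[1, ]; p$stenosis_degree <- 0; p$d_lad <- 3; p$d_lcx <- 3
  g <- build_bifurcation(p, length_factor = 3)
  m <- generate_mesh(g, 0.3)
  invg <- numeric(m$n_cells)
  invg[m$cells$branch == "LAD"] <- 1e16
  fl <- solve_flow(m, invg, boundary_conditions(2e-6), props,
                   advection = FALSE)
  br <- branch_flow_rates(fl, m)
  expect_lt(br$fractions[["outlet_1"]], 1e-3)
  ## velocity is negligible inside the penalized cells
  blocked <- m$cells$branch == "LAD" & m$cells$s_mm > 3
  speed <- sqrt(fl$uc[m$fluid]^2 + fl$vc[m$fluid]^2)[blocked]
  u_in <- fl$qbar / (3e-3)
  expect_lt(max(speed), 1e-6 * u_in * 10)
})

test_that("raising one branch's resistance monotonically starves it", {
  pt <- patient_table()
  p <- pt[1, ]; p$stenosis_degree <- 0; p$d_lad <- 3; p$d_lcx <- 3
  g <- build_bifurcation(p, length_factor = 3)
  m <- generate_mesh(g, 0.35)
  lad <- m$cells$branch == "LAD"
  fr <- vapply(10^seq(8, 15, length.out = 10), function(ig) {
    invg <- numeric(m$n_cells); invg[lad] <- ig
    fl <- solve_flow(m, invg, boundary_conditions(2e-6), props,
                     advection = FALSE)
    branch_flow_rates(fl, m)$fractions[["outlet_1"]]
  }, numeric(1))
  expect_true(all(diff(fr) < 1e-3))
  expect_lt(fr[10], fr[1] / 50)
})

test_that("Reynolds number follows rho U D / mu", {
  expect_equal(reynolds_number(10 / 6e7, 2e-3, props), 33.5, tolerance = 0.01)
  expect_equal(reynolds_number(0, 2e-3, props), 0)
  expect_equal(reynolds_number(2e-7, 2e-3, props) * 2,
               reynolds_number(4e-7, 2e-3, props))
})

test_that("wall shear along the stenosed tube peaks at the apex and dips after it", {
  g <- build_stenosed_tube(2, stenosis_spec(0.35, 4),
                           upstream_length = 4, downstream_length = 8)
  m <- generate_mesh(g, 0.1)
  fl <- solve_flow(m, NULL, boundary_conditions(10 / 6e7), props)
  ws <- wall_shear(fl, m, props)
  low <- ws[ws$side == "S", ]
  pre <- mean(low$gamma_dot[low$arclength_mm < 3])
  bins <- floor(low$arclength_mm * 2) / 2
  prof <- tapply(low$gamma_dot, bins, mean)
  xb <- as.numeric(names(prof))
  apex <- g$band[1] + 2    # bump center
  peak_x <- xb[which.max(prof)]
  expect_gt(max(prof), 2 * pre)                  # rises within the band
  expect_lt(abs(peak_x - apex), 1.01)            # peak near the apex
  ## post-stenotic region drops below the pre-stenosis level
  post <- prof[xb > g$band[2] - 1 & xb < g$band[2] + 1]
  expect_lt(min(post), pre)
})

test_that("flow solve errors carry the residual history on non-convergence", {
  g <- build_stenosed_tube(2, stenosis_spec(0.5, 4))
  m <- generate_mesh(g, 0.15)
  err <- tryCatch(
    solve_flow(m, NULL, boundary_conditions(60 / 6e7), props,
               max_iter = 3L, tol = 1e-10),
    error = function(e) e)
  expect_s3_class(err, "error")
  expect_true(length(err$residual_history) >= 3)
})

test_that("wall shear statistics stabilize under grid refinement", {
  g <- build_stenosed_tube(2, stenosis_spec(0.35, 4),
                           upstream_length = 4, downstream_length = 8)
  pk <- mn <- numeric(3)
  res <- c(0.2, 0.1, 0.05)
  for (k in 1:3) {
    m <- generate_mesh(g, res[k])
    fl <- solve_flow(m, NULL, boundary_conditions(10 / 6e7), props)
    ws <- wall_shear(fl, m, props)
    pk[k] <- stenosis_peak_shear(ws, bin_mm = 0.5)
    mn[k] <- mean(ws$tau_pa[ws$in_band])
  }
  ## the band-mean shear is grid-independent at the finest pair
  expect_lt(abs(mn[3] - mn[2]) / mn[3], 0.03)
  ## the staircase peak converges at first order: successive relative
  ## changes shrink
  d12 <- abs(pk[2] - pk[1]) / pk[3]
  d23 <- abs(pk[3] - pk[2]) / pk[3]
  expect_lt(d23, d12)
})
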