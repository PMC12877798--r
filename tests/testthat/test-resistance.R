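cp <- clot_parameters()

test_that("platelet resistance law has the half-maximum property", {
  expect_equal(platelet_inverse_permeability(0, cp), 0)
  expect_equal(platelet_inverse_permeability(cp$phi_cri, cp),
               cp$inv_g_dp_max / 2)
  cp2 <- clot_parameters(phi_cri = 0.5)
  expect_equal(platelet_inverse_permeability(1, cp2),
               cp2$inv_g_dp_max * 0.8)
  set.seed(11)
  for (k in 1:50) {
    pc <- runif(1, 0.05, 1)
    cpk <- clot_parameters(phi_cri = pc)
    expect_equal(platelet_inverse_permeability(pc, cpk),
                 cpk$inv_g_dp_max / 2, tolerance = 1e-15)
  }
})

test_that("Davis fibrin resistance matches direct arithmetic and is monotone", {
  expect_equal(fibrin_inverse_permeability(0), 0)
  expect_equal(fibrin_inverse_permeability(1, r_f = 55e-9),
               16 * 57 / (55e-9)^2, tolerance = 1e-12)
  expect_equal(fibrin_inverse_permeability(1, r_f = 55e-9), 3.015e17,
               tolerance = 1e-3)
  psi <- seq(0.01, 1, by = 0.01)
  expect_true(all(diff(fibrin_inverse_permeability(psi)) > 0))
})

test_that("fibrin fraction is the clamped ratio to inlet fibrinogen", {
  expect_equal(fibrin_fraction(0, 7), 0)
  expect_equal(fibrin_fraction(7, 7), 1)
  expect_equal(fibrin_fraction(3.5, 7), 0.5)
  expect_equal(fibrin_fraction(70, 7), 1)     # clamped
})

test_that("total resistance is the exact sum of its components", {
  expect_equal(total_inverse_permeability(0, 0), 0)
  expect_equal(total_inverse_permeability(3.2e14, 0), 3.2e14)
  a <- platelet_inverse_permeability(0.7, cp)
  b <- fibrin_inverse_permeability(0.4)
  expect_identical(total_inverse_permeability(a, b), a + b)
  expect_error(total_inverse_permeability(-1, 0))
})

test_that("clot propagation marks cells and exposes fresh surfaces", {
  g <- build_stenosed_tube(2, stenosis_spec(0.35, 4))
  m <- generate_mesh(g, 0.1)
  fcols <- c("cell", "i", "j", "side", "s_mm", "branch", "segment", "len")
  active0 <- m$faces[m$faces$in_band, fcols]
  dep <- wall_deposition_state(nrow(active0))
  rs <- resistance_field(m)
  ## nothing deposited: no clot, active set unchanged
  pc <- propagate_clot(rs, active0, dep, m, params = cp)
  expect_equal(sum(pc$resist$clot), 0)
  expect_equal(nrow(pc$active), nrow(active0))
  ## saturate one face: its cell joins the clot, neighbors become active
  dep$phi[1] <- 0.95; dep$q[1] <- 0.05
  target <- active0$cell[1]
  pc2 <- propagate_clot(pc$resist, pc$active, dep, m, params = cp)
  expect_true(pc2$resist$clot[target])
  expect_equal(pc2$n_new, 1L)
  ## the saturated face's cell is solid: dropped from the active set,
  ## fresh faces on its open neighbors appear with zero coverage
  expect_false(target %in% pc2$active$cell)
  old_keys <- paste(active0$cell, active0$side)
  new_keys <- paste(pc2$active$cell, pc2$active$side)
  fresh <- which(!(new_keys %in% old_keys))
  expect_gt(length(fresh), 0)
  expect_true(all(pc2$dep$phi[fresh] == 0))
  ## clot set never shrinks
  pc3 <- propagate_clot(pc2$resist, pc2$active, pc2$dep, m, params = cp)
  expect_true(all(pc3$resist$clot[pc2$resist$clot]))
})

test_that("fibrin adds resistance only where a platelet scaffold exists", {
  g <- build_stenosed_tube(2, stenosis_spec(0.35, 4))
  m <- generate_mesh(g, 0.1)
  fcols <- c("cell", "i", "j", "side", "s_mm", "branch", "segment", "len")
  active <- m$faces[m$faces$in_band, fcols]
  dep <- wall_deposition_state(nrow(active))
  rs <- resistance_field(m)
  c_f <- rep(3.5, m$n_cells)             # fibrin everywhere in plasma
  pc <- propagate_clot(rs, active, dep, m, c_f = c_f, c_fg_ref = 7,
                       params = cp)
  expect_true(all(pc$resist$inv_g_f == 0))   # no scaffold anywhere
  dep$phi[] <- 0.2; dep$q[] <- 0.8           # scaffold on the band walls
  pc2 <- propagate_clot(pc$resist, pc$active, dep, m, c_f = c_f,
                        c_fg_ref = 7, params = cp)
  expect_true(all(pc2$resist$inv_g_f[active$cell] > 0))
  off_band <- setdiff(seq_len(m$n_cells), active$cell)
  expect_true(all(pc2$resist$inv_g_f[off_band] == 0))
})
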