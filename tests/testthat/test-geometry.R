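test_that("packaged patient table matches the reference vessel characteristics", {
  pt <- patient_table()
  expect_s3_class(pt, "patient_parameters")
  expect_equal(nrow(pt), 6)
  p5 <- pt[5, ]
  expect_equal(p5$d_lmca, 4.80)
  expect_equal(p5$d_lad, 4.30)
  expect_equal(p5$d_lcx, 2.90)
  expect_equal(p5$stenosed_branch, "LAD")
  expect_equal(p5$stenosis_degree, 0.44)
  expect_equal(p5$stenosis_length, 6.00)
  p2 <- pt[2, ]
  expect_equal(p2$stenosed_branch, "LCX")
  expect_equal(p2$stenosis_degree, 0.71)
  expect_equal(p2$stenosis_length, 22.70)
})

test_that("stenosis profile is a smooth cosine bump with exact throat", {
  sp <- stenosis_spec(0.63, 6, center_position = 10)
  ## identity outside the bump, minimum at the center
  expect_equal(stenosis_profile(c(0, 6.9, 13.1, 20), 3.5, sp),
               rep(3.5, 4))
  expect_equal(stenosis_profile(10, 3.5, sp), 3.5 * (1 - 0.63))
  ## degree 0 is the identity everywhere
  sp0 <- stenosis_spec(0, 6, center_position = 10)
  s <- seq(0, 20, by = 0.1)
  expect_equal(stenosis_profile(s, 2.2, sp0), rep(2.2, length(s)))
  ## area-based degree converts to the equivalent diameter degree
  spa <- stenosis_spec(0.64, 6, center_position = 10, basis = "area")
  expect_equal(spa$degree_by_diameter, 1 - sqrt(1 - 0.64))
  expect_error(stenosis_spec(1, 6), "occlusion")
})

test_that("throat width is exact for random base/degree pairs", {
  set.seed(42)
  for (k in 1:100) {
    base <- runif(1, 1, 6); deg <- runif(1, 0, 0.95)
    sp <- stenosis_spec(deg, 8, center_position = 10)
    s <- seq(6, 14, length.out = 4001)
    w <- stenosis_profile(s, base, sp)
    expect_gt(min(w), 0)
    expect_equal(min(w), base * (1 - deg), tolerance = 1e-9)
  }
})

test_that("stenosed tube geometry labels the band and its segments", {
  g <- build_stenosed_tube(2, stenosis_spec(0.35, 4), n_segments = 5)
  expect_equal(min(branch_width(g, "tube", seq(0, g$length, by = 0.005))),
               2 * (1 - 0.35), tolerance = 1e-9)
  m <- generate_mesh(g, 0.1)
  segs <- m$faces$segment[m$faces$in_band]
  expect_setequal(unique(segs), 1:5)
  ## equal-arclength segments: spans agree within a cell
  spans <- tapply(m$faces$s_mm[m$faces$in_band], segs,
                  function(s) diff(range(s)))
  expect_lt(diff(range(spans)), 2 * 0.1 + 1e-9)
  ## degenerate stenosis still labels a band
  g0 <- build_stenosed_tube(2, stenosis_spec(0, 4))
  m0 <- generate_mesh(g0, 0.1)
  expect_gt(sum(m0$faces$in_band), 0)
  ## a stenosis longer than the branch is rejected
  pt <- patient_table()
  expect_error(build_bifurcation(pt[2, ], branch_length = 10,
                                 length_factor = 3), "too short")
})

test_that("bifurcation geometry is built from patient parameters", {
  pt <- patient_table()
  g <- build_bifurcation(pt[1, ], length_factor = 3)
  ## stenosed LAD throat from the table arithmetic
  s <- seq(g$band[1], g$band[2], length.out = 2001)
  expect_equal(min(branch_width(g, "LAD", s)), 3.50 * (1 - 0.63),
               tolerance = 1e-9)
  expect_equal(length(g$outlet_branches), 2L)
  m <- generate_mesh(g, 0.3)
  expect_setequal(unique(m$faces$label),
                  c("inlet", "outlet_1", "outlet_2", "wall"))
  ## equal daughters, no stenosis: mirror-symmetric mask
  p <- pt[1, ]; p$stenosis_degree <- 0; p$d_lad <- 3; p$d_lcx <- 3
  gs <- build_bifurcation(p, length_factor = 3)
  ms <- generate_mesh(gs, 0.3)
  expect_identical(ms$fluid, ms$fluid[, rev(seq_len(ms$ny))])
  expect_error(build_bifurcation(pt[1, ], half_angle = 0.5,
                                 length_factor = 3), "overlap")
})

test_that("patient CSV round-trips through the documented schema", {
  pt <- patient_table()
  f <- tempfile(fileext = ".csv")
  df <- data.frame(patient_id = pt$patient_id, d_lmca_mm = pt$d_lmca,
                   d_lad_mm = pt$d_lad, d_lcx_mm = pt$d_lcx,
                   stenosed_branch = pt$stenosed_branch,
                   stenosis_pct = pt$stenosis_degree * 100,
                   stenosis_len_mm = pt$stenosis_length)
  write.csv(df, f, row.names = FALSE)
  back <- read_patient_csv(f)
  expect_equal(back$stenosis_degree, pt$stenosis_degree)
  expect_equal(back$d_lmca, pt$d_lmca)
})

test_that("the eccentric stenosis narrows from one wall only", {
  g <- build_stenosed_tube(2, stenosis_spec(0.5, 4), eccentric = TRUE)
  m <- generate_mesh(g, 0.1)
  expect_true(all(m$fluid[, 1]))          # flat lower wall
  expect_false(all(m$fluid[, m$ny]))      # bump carved from the upper wall
  s <- seq(0, g$length, by = 0.01)
  expect_equal(min(branch_width(g, "tube", s)), 1, tolerance = 1e-9)
})
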