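test_that("zero-LET McNamara RBE reduces to the closed form with RBE_max = p0, RBE_min = p2", {
  p0 <- 0.99064; p2 <- 1.1012
  for (ab in c(2, 3, 10)) {
    for (d in c(0.5, 2, 5)) {
      expected <- (sqrt(ab^2 + 4 * d * ab * p0 + 4 * d^2 * p2^2) - ab) / (2 * d)
      expect_equal(rbe_mcnamara(d, 0, ab), expected, tolerance = 1e-12)
    }
  }
  # D_p = 0 returns the analytic limit RBE_max
  expect_equal(rbe_mcnamara(0, 8, 2), 0.99064 + 0.35605 * 8 / 2)
})

test_that("vectorized McNamara RBE matches the independent scalar oracle on a 10^3 grid", {
  doses <- c(0, 0.5, 1, 1.8, 2.5, 4, 6, 10, 20, 50)
  lets <- c(0, 0.5, 1, 2, 3, 5, 8, 12, 16, 20)
  abs_ <- c(0.5, 1, 2, 2.45, 3, 4, 6, 8, 10, 15)
  grid <- expand.grid(d = doses, l = lets, ab = abs_)
  got <- rbe_mcnamara(grid$d, grid$l, grid$ab)
  expected <- vapply(seq_len(nrow(grid)), function(i) {
    mcnamara_scalar_oracle(grid$d[i], grid$l[i], grid$ab[i])
  }, numeric(1))
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("RBE trends: increasing in LET, decreasing in (alpha/beta)_x, approaching RBE_min at large dose", {
  lets <- seq(0, 20, by = 0.5)
  for (ab in c(2, 4, 10)) {
    expect_true(all(diff(rbe_mcnamara(2, lets, ab)) >= 0))
  }
  # low (alpha/beta)_x boosts RBE at fixed dose and LET (LET >= 1)
  abs_ <- c(2, 3, 4, 6, 10)
  for (l in c(1, 4, 8, 15)) {
    expect_true(all(diff(rbe_mcnamara(2, l, abs_)) <= 0))
  }
  expect_gt(rbe_mcnamara(2, 8, 2), rbe_mcnamara(2, 8, 10))
  # large-dose asymptote
  for (l in c(2, 8)) {
    rmin <- 1.1012 - 0.0038703 * sqrt(3) * l
    expect_lt(abs(rbe_mcnamara(1e5, l, 3) - rmin), 1e-3)
  }
})

test_that("negative inputs are rejected", {
  expect_error(rbe_mcnamara(-1, 2, 2))
  expect_error(rbe_mcnamara(1, -2, 2))
  expect_error(rbe_mcnamara(1, 2, -2))
})

test_that("constant-RBE weighting is exactly 1.1 times the physical dose", {
  pl <- small_plan()
  g <- rbe_weighted_dose(pl$dose, model = "constant_1p1")
  expect_identical(g$values, pl$dose$values * 1.1)
  expect_equal(g$unit, "Gy(RBE)")
})

test_that("variable RBE at (alpha/beta)_x = 2 raises the mean CTV dose above the constant-1.1 value", {
  ph <- small_phantom()
  pl <- small_plan()
  g2 <- rbe_weighted_dose(pl$dose, pl$letd, "mcnamara", alpha_beta_x = 2,
                          n_fractions = pl$prescription$n_fractions)
  g11 <- rbe_weighted_dose(pl$dose, model = "constant_1p1")
  ctv <- ph$structures$CTV
  expect_gt(mean(g2$values[ctv]), mean(g11$values[ctv]))
})

test_that("a high tumor (alpha/beta)_x of 10 lowers CTV D95 below the matched-2-Gy value", {
  ph <- small_phantom()
  pl <- small_plan()
  nfx <- pl$prescription$n_fractions
  g_matched <- rbe_weighted_dose(pl$dose, pl$letd, "mcnamara",
                                 alpha_beta_x = 2, n_fractions = nfx)
  g_ctv10 <- rbe_weighted_dose(pl$dose, pl$letd, "mcnamara",
                               alpha_beta_x = c(.default = 2, CTV = 10),
                               n_fractions = nfx, ph = ph)
  d95m <- ctv_coverage(g_matched, ph)$d95
  d95h <- ctv_coverage(g_ctv10, ph)$d95
  expect_lt(d95h, d95m)
})

test_that("voxels excluded by the LET threshold fall back to RBE 1.1", {
  pl <- small_plan()
  g <- rbe_weighted_dose(pl$dose, pl$letd, "mcnamara", alpha_beta_x = 2,
                         n_fractions = 39)
  excl <- attr(pl$letd, "excluded")
  expect_equal(g$values[excl], 1.1 * pl$dose$values[excl])
})

test_that("fractionation conversion: identity, derived value, large alpha/beta limit and round trip", {
  # d1 = d2 leaves the constraint unchanged
  expect_equal(eqd_convert(54, d2 = 2, d1 = 2, alpha_beta_x = 2), 54,
               tolerance = 1e-15)
  # adult scheme: d1 = 65.13/39 = 1.67 Gy(RBE); direct arithmetic oracle
  d1 <- 65.13 / 39
  expect_equal(eqd_convert(60, d2 = 2, d1 = d1, alpha_beta_x = 2),
               60 * (1 + 2 / 2) / (1 + 1.67 / 2), tolerance = 1e-12)
  expect_equal(eqd_convert(60, d2 = 2, d1 = d1, alpha_beta_x = 2),
               65.39509536784741, tolerance = 1e-10)
  # very large (alpha/beta)_x: conversion disappears
  expect_lt(abs(eqd_convert(60, 2, 1.67, 1e6) - 60) / 60, 0.001)
  # round trip recovers D2 to machine precision
  D1 <- eqd_convert(54, d2 = 2, d1 = 1.8, alpha_beta_x = 3)
  expect_equal(eqd_convert(D1, d2 = 1.8, d1 = 2, alpha_beta_x = 3), 54,
               tolerance = 1e-14)
  expect_error(eqd_convert(54, 2, 2, alpha_beta_x = 0))
})

test_that("the shipped EQD2-style table converts to the adult scheme", {
  tab <- eqd2_constraints()
  expect_true(all(c("structure", "limit_eqd2", "alpha_beta_x") %in% names(tab)))
  conv <- eqd_convert_table(tab, d1 = prescription("adult")$dose_per_fraction_gy_rbe)
  # 1.67 < 2 Gy per fraction, so converted limits exceed the EQD2 values
  expect_true(all(conv$limit_converted > conv$limit_eqd2))
})
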