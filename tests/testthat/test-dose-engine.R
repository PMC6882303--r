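test_that("single-beam dose on a uniform phantom is proportional to the SOBP curve along the central axis", {
  ph <- small_phantom()
  pl <- single_beam_plan()
  ctr <- protonplan:::voxel_centers(ph)
  iso <- pl$isocenter
  onaxis <- which(abs(ctr[, 1] - iso[1]) < 2.5 & abs(ctr[, 3] - iso[3]) < 2.5)
  depth <- water_depth(ph, pl$fields[[1]]$basis$u)[onaxis]
  cur <- protonplan:::sobp_depth_curves(pl$fields[[1]]$fit, depth / 10)
  d <- pl$dose$values[onaxis]
  ok <- is.finite(depth) & !is.na(cur$dose) &
    cur$dose > 0.05 * max(cur$dose, na.rm = TRUE)
  ratio <- d[ok] / cur$dose[ok]
  expect_lt(stats::sd(ratio) / mean(ratio), 1e-10)
})

test_that("the 4-field star normalizes median CTV dose to the prescription under RBE 1.1", {
  ph <- small_phantom()
  pl <- small_plan()
  per_fx <- 1.1 * median(pl$dose$values[ph$structures$CTV]) /
    pl$prescription$n_fractions
  target <- pl$prescription$total_gy_rbe / pl$prescription$n_fractions
  expect_lt(abs(per_fx - target) / target, 0.005)
})

test_that("scaling all field weights is removed by normalization", {
  ph <- small_phantom()
  beams <- beam_star()
  beams$weight <- 2 * beams$weight
  pl2 <- plan_proton(ph, beams = beams)
  expect_equal(pl2$dose$values, small_plan()$dose$values, tolerance = 1e-12)
})

test_that("dose-averaged LET of a mixture is the dose-weighted mean and stays within component bounds", {
  # two equal contributions at 2 and 6 keV/um average to 4
  expect_equal(dose_averaged_let(list(1, 1), list(2, 6), 0)[1], 4)
  # random 3-field toy case against a scalar accumulation oracle
  set.seed(31)
  n <- 200
  doses <- lapply(1:3, function(i) runif(n))
  lets <- lapply(1:3, function(i) runif(n, 0.5, 12))
  got <- dose_averaged_let(doses, lets, threshold_frac = 0.005)
  expected <- numeric(n)
  for (v in seq_len(n)) {
    num <- 0; den <- 0
    for (f in 1:3) {
      num <- num + doses[[f]][v] * lets[[f]][v]
      den <- den + doses[[f]][v]
    }
    expected[v] <- num / den
  }
  thr <- 0.005 * max(Reduce(`+`, doses))
  keep <- Reduce(`+`, doses) >= thr
  expect_equal(got[keep], expected[keep], tolerance = 1e-12)
  # convexity: mixture LET within [min, max] of components
  lo <- pmin(lets[[1]], lets[[2]], lets[[3]])
  hi <- pmax(lets[[1]], lets[[2]], lets[[3]])
  expect_true(all(got[keep] >= lo[keep] - 1e-12 & got[keep] <= hi[keep] + 1e-12))
})

test_that("the LET map applies the 0.5%-of-max dose threshold exactly", {
  pl <- small_plan()
  thr <- 0.005 * max(pl$dose$values)
  excluded <- attr(pl$letd, "excluded")
  expect_identical(excluded, pl$dose$values < thr)
  expect_true(all(pl$letd$values[excluded] == 0))
  expect_true(all(pl$letd$values[!excluded] > 0))
})

test_that("single-field LET_d rises monotonically toward the distal edge and the distal rim exceeds the CTV", {
  ph <- small_phantom()
  pl <- single_beam_plan()
  fld <- pl$fields[[1]]
  depth <- water_depth(ph, fld$basis$u)
  ctr <- protonplan:::voxel_centers(ph)
  onaxis <- which(abs(ctr[, 1] - pl$isocenter[1]) < 2.5 &
                    abs(ctr[, 3] - pl$isocenter[3]) < 2.5 &
                    !as.vector(attr(pl$letd, "excluded")))
  d <- depth[onaxis]
  ord <- order(d)
  let_axis <- pl$letd$values[onaxis][ord]
  d <- d[ord]
  zg <- seq(0, fld$fit$range_cm + 1, by = 0.01)
  comp <- protonplan:::sobp_depth_curves(fld$fit, zg)$dose
  distal80 <- 10 * max(zg[comp >= 0.8 * max(comp)])
  upto <- d <= distal80
  expect_true(all(diff(let_axis[upto]) > -1e-9))

  # high-LET rim: mean LET in a 5 mm shell beyond the distal edge exceeds
  # the mean LET inside the CTV
  edge <- 10 * fld$fit$range_cm
  shell <- is.finite(depth) & depth > edge & depth <= edge + 5 &
    !as.vector(attr(pl$letd, "excluded"))
  ctv <- as.vector(ph$structures$CTV)
  expect_gt(mean(pl$letd$values[shell]), mean(pl$letd$values[ctv]))
})

test_that("unit tags guard grid arithmetic", {
  a <- dose_grid(array(1, c(2, 2, 2)), "Gy")
  b <- dose_grid(array(2, c(2, 2, 2)), "Gy")
  l <- dose_grid(array(3, c(2, 2, 2)), "keV/um")
  expect_equal((a + b)$values, array(3, c(2, 2, 2)))
  expect_error(a + l, "unit mismatch")
  expect_error(dose_grid(array(-1, c(2, 2, 2)), "Gy"), "non-negative")
  expect_error(dose_grid(array(1, c(2, 2, 2)), unit = 3), "unit")
  expect_error(rbe_weighted_dose(l, model = "constant_1p1"), "Gy")
})

test_that("planning fails when the target is empty", {
  ph <- small_phantom()
  ph$structures$CTV[] <- FALSE
  expect_error(plan_proton(ph), "CTV|empty|missing")
})
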