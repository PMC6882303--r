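make_grid <- function(vals, dim3) dose_grid(array(vals, dim3), "Gy(RBE)")

test_that("a uniform dose gives a step-function DVH", {
  dim3 <- c(8, 8, 8)
  mask <- array(TRUE, dim3)
  g <- make_grid(10, dim3)
  dvh <- compute_dvh(g, mask, bin_gy = 0.05, voxel_cm3 = 0.064)
  expect_equal(dvh$volume_frac[dvh$dose <= 10], rep(1, sum(dvh$dose <= 10)))
  expect_equal(dvh$volume_frac[dvh$dose > 10], rep(0, sum(dvh$dose > 10)))
  expect_equal(max(dvh$volume_cm3), sum(mask) * 0.064)
})

test_that("cumulative DVHs are monotone non-increasing and start at 100%", {
  set.seed(5)
  dim3 <- c(10, 10, 10)
  g <- make_grid(runif(1000, 0, 70), dim3)
  dvh <- compute_dvh(g, array(TRUE, dim3), bin_gy = 0.05, voxel_cm3 = 0.008)
  expect_true(all(diff(dvh$volume_frac) <= 0))
  expect_equal(dvh$volume_frac[1], 1)
  expect_equal(utils::tail(dvh$volume_frac, 1), 0)
})

test_that("DVH statistics agree with voxel-sorting oracles on 50 randomized grids", {
  set.seed(1234)
  bin <- 0.05
  vox <- 0.064
  for (rep_i in 1:50) {
    dim3 <- c(sample(6:12, 1), sample(6:12, 1), sample(6:12, 1))
    n <- prod(dim3)
    mask <- array(runif(n) < 0.6, dim3)
    if (sum(mask) < 20) mask[1:20] <- TRUE
    vals <- array(runif(n, 0, 70)^1.2 / 70^0.2, dim3)
    g <- dose_grid(vals, "Gy(RBE)")
    dvh <- compute_dvh(g, mask, bin_gy = bin, voxel_cm3 = vox)
    orc <- sort_oracle(vals[mask], vox)
    # D0.1cc and D at 50% volume within one bin width
    expect_lte(abs(dose_at_volume(dvh, volume_cm3 = 0.1) - orc$d_at_vol(0.1)),
               bin + 1e-9)
    half <- attr(dvh, "total_cm3") / 2
    expect_lte(abs(dose_at_volume(dvh, volume_cm3 = half) - orc$d_at_vol(half)),
               bin + 1e-9)
    # D95 within one bin width
    v95 <- 0.95 * attr(dvh, "total_cm3")
    expect_lte(abs(dose_at_volume(dvh, volume_pct = 95) - orc$d_at_vol(v95)),
               bin + 1e-9)
    # V >= dose within ~one voxel volume
    for (dd in c(10, 35, 58)) {
      expect_lte(abs(volume_at_dose(dvh, dd) - orc$v_at_dose(dd)), 1.5 * vox)
    }
  }
})

test_that("two-level dose: hottest 0.1 cm^3 sits in the hot region", {
  # hot 0.2 cm^3 at 60 Gy, remainder at 20 Gy
  vox <- 0.05
  dim3 <- c(10, 10, 10)
  vals <- array(20, dim3)
  vals[1:4] <- 60  # 4 voxels x 0.05 cm^3 = 0.2 cm^3
  g <- dose_grid(vals, "Gy(RBE)")
  dvh <- compute_dvh(g, array(TRUE, dim3), bin_gy = 0.05, voxel_cm3 = vox)
  expect_equal(dose_at_volume(dvh, volume_cm3 = 0.1), 60, tolerance = 0.051)
})

test_that("DVH edge conventions", {
  dim3 <- c(6, 6, 6)
  set.seed(8)
  vals <- array(runif(216, 5, 40), dim3)
  g <- dose_grid(vals, "Gy(RBE)")
  dvh <- compute_dvh(g, array(TRUE, dim3), bin_gy = 0.05, voxel_cm3 = 0.008)
  total <- attr(dvh, "total_cm3")
  expect_lte(abs(dose_at_volume(dvh, volume_cm3 = total) - min(vals)), 0.051)
  expect_equal(volume_at_dose(dvh, 0), total)
  expect_equal(volume_at_dose(dvh, 100), 0)
  expect_error(dose_at_volume(dvh, volume_cm3 = total * 2), "exceeds")
  expect_error(compute_dvh(g, array(FALSE, dim3), voxel_cm3 = 0.008), "empty")
})

test_that("constraint evaluation uses the proper statistic and boundary conventions", {
  ph <- small_phantom()
  dim3 <- ph$dim
  cons <- constraint_set("adult", structures = names(ph$structures))
  # uniform 57 Gy(RBE): D0.1cc = 57 passes against the 58 limit
  g <- dose_grid(array(57, dim3), "Gy(RBE)")
  rep1 <- suppressWarnings(evaluate_constraints(g, ph, cons))
  bs <- rep1[rep1$structure == "brainstem", ]
  expect_equal(bs$value, 57, tolerance = 0.06)
  expect_false(bs$breach)
  # dose exactly at the limit counts as "at or above" = breach
  g58 <- dose_grid(array(58, dim3), "Gy(RBE)")
  rep2 <- evaluate_constraints(g58, ph, cons)
  expect_true(all(rep2$breach[rep2$type == "dvol"]))
  # pediatric brainstem limit is 50.4 Gy(RBE)
  ped <- constraint_set("pediatric")
  expect_equal(ped$limit[ped$structure == "brainstem"], 50.4)
  expect_equal(constraint_set("adult")$limit[
    constraint_set("adult")$structure == "brainstem"], 58)
  # missing structure: explicit warning, rule skipped
  full <- constraint_set("adult")
  warns <- capture_warnings(rep3 <- evaluate_constraints(g, ph, full))
  expect_true(any(grepl("spinal_cord", warns)))
  expect_true(any(grepl("parotid", warns)))
  expect_false("spinal_cord" %in% rep3$structure)
})

test_that("V at-or-above the limit never exceeds the structure volume", {
  ph <- small_phantom()
  pl <- small_plan()
  g <- rbe_weighted_dose(pl$dose, model = "constant_1p1")
  rep1 <- evaluate_constraints(g, ph,
                               constraint_set("adult",
                                              structures = names(ph$structures)))
  sv <- structure_volumes(ph)
  for (r in seq_len(nrow(rep1))) {
    tot <- sv$volume_cm3[sv$structure == rep1$structure[r]]
    expect_lte(rep1$v_ge_limit_cm3[r], tot + 1e-9)
  }
})
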