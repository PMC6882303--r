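test_that("CTV volume matches the requested volume within one voxel", {
  for (case in list(list(vol = 20, vox = 2), list(vol = 30, vox = 4),
                    list(vol = 12, vox = 5))) {
    ph <- build_phantom(phantom_spec("adult", voxel_mm = case$vox,
                                     target_volume_cm3 = case$vol,
                                     random_seed = 11))
    vv <- prod(ph$voxel_mm) / 1000
    got <- sum(ph$structures$CTV) * vv
    expect_lte(abs(got - case$vol), vv + 1e-12)
  }
})

test_that("required structures exist, volumes are count times voxel volume, and all structures lie inside the external contour", {
  ph <- small_phantom()
  expect_setequal(names(ph$structures),
                  c("CTV", "brainstem", "optic_chiasm", "optic_nerve_L",
                    "optic_nerve_R", "brain", "external"))
  sv <- structure_volumes(ph)
  vv <- prod(ph$voxel_mm) / 1000
  expect_equal(sv$volume_cm3, sv$n_voxels * vv)
  ext <- ph$structures$external
  for (nm in setdiff(names(ph$structures), "external")) {
    expect_false(any(ph$structures[[nm]] & !ext), label = nm)
  }
  expect_true(all(ph$density[!ext] == 0))
  expect_true(all(ph$density[ext] > 0))
})

test_that("chiasm overlap fraction is achieved within one voxel", {
  for (f in c(0.5, 0.7, 0.9)) {
    ph <- build_phantom(phantom_spec("adult", voxel_mm = 4,
                                     chiasm_overlap_fraction = f,
                                     random_seed = 5))
    n_ch <- sum(ph$structures$optic_chiasm)
    ov <- sum(ph$structures$optic_chiasm & ph$structures$CTV)
    expect_lte(abs(ov - round(f * n_ch)), 1)
  }
})

test_that("full chiasm overlap forces set inclusion in the CTV", {
  ph <- build_phantom(phantom_spec("adult", voxel_mm = 4,
                                   chiasm_overlap_fraction = 1, random_seed = 2))
  expect_false(any(ph$structures$optic_chiasm & !ph$structures$CTV))
})

test_that("identical spec and seed give a bit-identical phantom", {
  sp <- phantom_spec("pediatric", voxel_mm = 5, random_seed = 42)
  expect_identical(build_phantom(sp)$structures, build_phantom(sp)$structures)
})

test_that("an infeasible spec raises a geometry error", {
  expect_error(build_phantom(phantom_spec("adult", voxel_mm = 4,
                                          target_volume_cm3 = 5000)),
               "infeasible")
})

test_that("cohort sampling mixes classes 6/4 at n = 10 and is seed-deterministic", {
  co <- sample_cohort(10, phantom_spec(voxel_mm = 6), seed = 3)
  classes <- vapply(co, function(p) p$patient_class, character(1))
  expect_equal(sum(classes == "adult"), 6)
  expect_equal(sum(classes == "pediatric"), 4)
  co2 <- sample_cohort(10, phantom_spec(voxel_mm = 6), seed = 3)
  expect_identical(lapply(co, `[[`, "structures"),
                   lapply(co2, `[[`, "structures"))
  # different seed changes at least one mask
  co3 <- sample_cohort(10, phantom_spec(voxel_mm = 6), seed = 4)
  expect_false(identical(lapply(co, `[[`, "structures"),
                         lapply(co3, `[[`, "structures")))
  # singleton cohort works
  expect_length(sample_cohort(1, phantom_spec(voxel_mm = 6), seed = 1), 1)
})

test_that("phantom serialization round-trips through NIfTI + sidecar", {
  ph <- small_phantom()
  dir <- withr::local_tempdir()
  write_phantom(ph, dir)
  ph2 <- read_phantom(dir)
  expect_identical(ph2$structures, ph$structures)
  expect_equal(ph2$density, ph$density, tolerance = 1e-6)
  expect_equal(ph2$voxel_mm, ph$voxel_mm)
  expect_equal(ph2$patient_class, ph$patient_class)
})

test_that("prescription presets carry the clinical schemes", {
  ad <- prescription("adult")
  pe <- prescription("pediatric")
  expect_equal(ad$total_gy_rbe, 65.13)
  expect_equal(ad$n_fractions, 39L)
  expect_equal(pe$total_gy_rbe, 50.4)
  expect_equal(pe$n_fractions, 28L)
})
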