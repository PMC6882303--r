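# Shared fixtures, built lazily and memoized for the whole test session.
.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

# Small adult phantom (5 mm grid) used by most engine tests.
small_phantom <- function() {
  memo("small_phantom", function() {
    build_phantom(phantom_spec("adult", voxel_mm = 5, random_seed = 7))
  })
}

# Four-field plan on the small phantom.
small_plan <- function() {
  memo("small_plan", function() plan_proton(small_phantom()))
}

# Single anterior field plan (beam travels along -y).
single_beam_plan <- function() {
  memo("single_beam_plan", function() {
    plan_proton(small_phantom(), beams = beam_spec(0, 0))
  })
}

small_robustness <- function() {
  memo("small_robustness", function() {
    robustness_analysis(small_plan(), small_phantom())
  })
}

# The default study conditions: 6 adult + 4 pediatric phantoms on a 4 mm
# grid, fixed seed. Built once; used by the cohort-level tests.
default_study <- function() {
  memo("default_study", function() run_study(study_config(seed = 1L)))
}

# Hand-built rotationally symmetric phantom (spherical head, centered
# spherical CTV) for the arc-symmetry test. Mimics an externally
# supplied phantom.
symmetric_phantom <- function(voxel = 4) {
  memo("symmetric_phantom", function() {
    n <- as.integer(2 * ceiling(75 / voxel) + 1)
    dim3 <- c(n, n, n)
    origin <- -(n - 1) / 2 * voxel * c(1, 1, 1)
    ax <- origin[1] + (seq_len(n) - 1) * voxel
    X <- array(rep(ax, times = n * n), dim3)
    Y <- array(rep(rep(ax, each = n), times = n), dim3)
    Z <- array(rep(ax, each = n * n), dim3)
    r2 <- X^2 + Y^2 + Z^2
    external <- r2 <= 60^2
    ctv <- r2 <= 15^2
    density <- array(0, dim3); density[external] <- 1
    dummy <- array(FALSE, dim3); dummy[1, 1, 1] <- TRUE
    structure(list(
      dim = dim3, voxel_mm = rep(voxel, 3), origin_mm = origin,
      density = density,
      structures = list(CTV = ctv, brainstem = ctv, optic_chiasm = ctv,
                        optic_nerve_L = ctv, optic_nerve_R = ctv,
                        brain = external, external = external),
      patient_class = "adult", uniform_density = TRUE,
      shapes = list(external = list(center = c(0, 0, 0), semi = rep(60, 3)),
                    ctv = list(center = c(0, 0, 0), semi = rep(15, 3))),
      spec = NULL
    ), class = "phantom")
  })
}

# Independent scalar implementation of the McNamara closed form, coded
# separately from the vectorized path (plain loops, no recycling).
mcnamara_scalar_oracle <- function(d, l, ab) {
  p0 <- 0.99064; p1 <- 0.35605; p2 <- 1.1012; p3 <- -0.0038703
  rmax <- p0 + p1 * l / ab
  rmin <- max(p2 + p3 * sqrt(ab) * l, 0)
  if (d == 0) return(rmax)
  (sqrt(ab^2 + 4 * d * ab * rmax + 4 * d^2 * rmin^2) - ab) / (2 * d)
}

# Sort-based DVH statistics oracle, independent of the binned DVH path.
sort_oracle <- function(doses, voxel_cm3) {
  sorted <- sort(doses, decreasing = TRUE)
  list(
    d_at_vol = function(v_cm3) sorted[max(1, ceiling(v_cm3 / voxel_cm3))],
    v_at_dose = function(d) sum(doses >= d) * voxel_cm3,
    mean = mean(doses)
  )
}
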