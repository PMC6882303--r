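#' Specify a synthetic base-of-skull phantom
#'
#' A `phantom_spec` holds every parameter needed to build a reproducible
#' voxel phantom that emulates the treatment-site topology of base-of-skull
#' sarcoma/chordoma and pediatric craniopharyngioma cases: a centrally
#' located clinical target volume (CTV) that partially overlaps the small
#' optic chiasm, a brainstem directly posterior to (by default abutting) the
#' CTV, and paired optic nerves running anterolaterally from the chiasm,
#' all inside a brain and an external (head) contour.
#'
#' Structures are analytic solids (ellipsoids, an elliptic cylinder for the
#' brainstem, capsule segments for the optic nerves) rasterized onto a
#' regular grid; a voxel belongs to a structure iff its center is inside the
#' solid. The CTV and chiasm are rasterized to an exact voxel count (the
#' voxels with smallest ellipsoid norm), so their volumes match the request
#' to within half a voxel.
#'
#' @param patient_class `"adult"` (chondrosarcoma/chordoma-like geometry and
#'   prescription, 65.13 Gy(RBE) in 39 fractions) or `"pediatric"`
#'   (craniopharyngioma-like, 50.4 Gy(RBE) in 28 fractions).
#' @param random_seed Integer seed; identical spec + seed gives a
#'   bit-identical phantom.
#' @param target_volume_cm3 CTV volume in cm^3. Defaults: 30 (adult),
#'   18 (pediatric).
#' @param chiasm_overlap_fraction Fraction of the chiasm volume inside the
#'   CTV, in `[0, 1]`. Default 0.7 (the majority of the chiasm sits inside
#'   the target, as is typical for this site).
#' @param brainstem_gap_mm CTV-to-brainstem margin in mm; 0 (default) means
#'   the brainstem abuts the CTV.
#' @param voxel_mm Isotropic voxel size in mm (scalar) or a length-3 vector.
#' @param chiasm_volume_cm3 Chiasm volume in cm^3 (default 0.9 adult,
#'   0.7 pediatric; clinical chiasm volumes are well below 1 cm^3).
#' @param head_scale Global scale factor applied to head/brain geometry.
#' @param ctv_aspect Length-3 semi-axis aspect ratio of the CTV ellipsoid.
#' @param external_semi_mm Optional length-3 semi-axes (mm) of the external
#'   head ellipsoid, overriding the per-class preset.
#' @param center_jitter_vox Sub-voxel jitter (in voxel units) applied to
#'   structure centers to break rasterization ties. Set to 0 for exactly
#'   symmetric phantoms.
#' @param bone_shell If `TRUE`, add a bone-like density shell (relative
#'   stopping power 1.6) under the external surface. Default `FALSE`:
#'   uniform water-equivalent density, matching beam paths chosen to avoid
#'   heterogeneous regions.
#'
#' @return An object of class `phantom_spec` (a named list).
#' @seealso [build_phantom()], [sample_cohort()]
#' @export
phantom_spec <- function(patient_class = c("adult", "pediatric"),
                         random_seed = 1L,
                         target_volume_cm3 = NULL,
                         chiasm_overlap_fraction = 0.7,
                         brainstem_gap_mm = 0,
                         voxel_mm = 2,
                         chiasm_volume_cm3 = NULL,
                         head_scale = 1,
                         ctv_aspect = c(1, 1.08, 0.92),
                         external_semi_mm = NULL,
                         center_jitter_vox = 0.3,
                         bone_shell = FALSE) {
  patient_class <- match.arg(patient_class)
  if (is.null(target_volume_cm3)) {
    target_volume_cm3 <- if (patient_class == "adult") 30 else 18
  }
  if (is.null(chiasm_volume_cm3)) {
    chiasm_volume_cm3 <- if (patient_class == "adult") 0.9 else 0.7
  }
  if (length(voxel_mm) == 1) voxel_mm <- rep(voxel_mm, 3)
  stopifnot(
    length(voxel_mm) == 3, all(voxel_mm > 0),
    target_volume_cm3 > 0,
    chiasm_overlap_fraction >= 0, chiasm_overlap_fraction <= 1,
    brainstem_gap_mm >= 0,
    head_scale > 0, length(ctv_aspect) == 3, all(ctv_aspect > 0)
  )
  spec <- list(
    patient_class = patient_class,
    random_seed = as.integer(random_seed),
    target_volume_cm3 = target_volume_cm3,
    chiasm_overlap_fraction = chiasm_overlap_fraction,
    brainstem_gap_mm = brainstem_gap_mm,
    voxel_mm = as.numeric(voxel_mm),
    chiasm_volume_cm3 = chiasm_volume_cm3,
    head_scale = head_scale,
    ctv_aspect = as.numeric(ctv_aspect),
    external_semi_mm = external_semi_mm,
    center_jitter_vox = center_jitter_vox,
    bone_shell = isTRUE(bone_shell)
  )
  structure(spec, class = "phantom_spec")
}

# Per-class analytic geometry presets (mm, CTV centered at the origin;
# +x left, +y anterior, +z superior).
phantom_geometry <- function(spec) {
  s <- spec$head_scale
  if (spec$patient_class == "adult") {
    g <- list(
      external_c = c(0, 5, 25), external_semi = c(75, 92, 80),
      brain_c = c(0, 5, 24), brain_semi = c(64, 78, 64),
      brainstem_semi2d = c(9, 11), brainstem_z = c(-45, 20),
      nerve_radius = 2.8, nerve_length = 26
    )
  } else {
    g <- list(
      external_c = c(0, 4, 22), external_semi = c(65, 82, 72),
      brain_c = c(0, 4, 21), brain_semi = c(56, 70, 57),
      brainstem_semi2d = c(8, 10), brainstem_z = c(-40, 18),
      nerve_radius = 2.6, nerve_length = 24
    )
  }
  if (!is.null(spec$external_semi_mm)) g$external_semi <- spec$external_semi_mm
  g$external_semi <- g$external_semi * s
  g$brain_semi <- g$brain_semi * s
  g$external_c <- g$external_c * s
  g$brain_c <- g$brain_c * s
  g
}

#' Build a synthetic phantom from a spec
#'
#' Rasterizes the analytic geometry of a [phantom_spec()] onto a regular
#' voxel grid. The grid is sized to contain the external contour plus a
#' 2 cm margin; world coordinates are mm at voxel centers with the CTV
#' centroid at the origin. The chiasm center is positioned by bisection
#' along an anterosuperior axis so that the requested CTV overlap fraction
#' is met to within one voxel.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom`: a list with elements `dim`
#'   (grid shape), `voxel_mm`, `origin_mm` (world coordinate of the first
#'   voxel center), `density` (3D array, water = 1), `structures` (named
#'   list of logical 3D masks: `CTV`, `brainstem`, `optic_chiasm`,
#'   `optic_nerve_L`, `optic_nerve_R`, `brain`, `external`),
#'   `patient_class`, `shapes` (analytic solids used, for fast ray
#'   tracing), and `spec`.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- phantom_geometry(spec)
  vox <- spec$voxel_mm
  vol_vox_cm3 <- prod(vox) / 1000

  margin <- 20
  lo <- g$external_c - g$external_semi - margin
  hi <- g$external_c + g$external_semi + margin
  dim3 <- as.integer(ceiling((hi - lo) / vox))
  origin <- lo + vox / 2

  withr::with_seed(spec$random_seed, {
    jit <- function() runif(3, -1, 1) * spec$center_jitter_vox * vox

    ax <- lapply(1:3, function(i) origin[i] + (seq_len(dim3[i]) - 1) * vox[i])
    X <- array(rep(ax[[1]], times = dim3[2] * dim3[3]), dim3)
    Y <- array(rep(rep(ax[[2]], each = dim3[1]), times = dim3[3]), dim3)
    Z <- array(rep(ax[[3]], each = dim3[1] * dim3[2]), dim3)

    in_ellipsoid <- function(cen, semi) {
      ((X - cen[1]) / semi[1])^2 + ((Y - cen[2]) / semi[2])^2 +
        ((Z - cen[3]) / semi[3])^2 <= 1
    }
    external <- in_ellipsoid(g$external_c, g$external_semi)
    brain <- in_ellipsoid(g$brain_c, g$brain_semi) & external

    # CTV: exact-count rasterization of an ellipsoid with the requested
    # volume; the n voxels (inside the brain) with smallest ellipsoid norm.
    ctv_c <- jit()
    asp <- spec$ctv_aspect
    s_ctv <- (spec$target_volume_cm3 * 1000 / (4 / 3 * pi * prod(asp)))^(1 / 3)
    ctv_semi <- s_ctv * asp
    n_ctv <- max(1L, round(spec$target_volume_cm3 / vol_vox_cm3))
    m_ctv <- ((X - ctv_c[1]) / ctv_semi[1])^2 + ((Y - ctv_c[2]) / ctv_semi[2])^2 +
      ((Z - ctv_c[3]) / ctv_semi[3])^2
    m_ctv[!brain] <- Inf
    if (sum(is.finite(m_ctv)) < n_ctv) {
      abort("CTV does not fit inside the brain volume: infeasible phantom spec.")
    }
    thr_ctv <- sort.int(as.vector(m_ctv), partial = n_ctv)[n_ctv]
    ctv <- m_ctv <= thr_ctv
    # resolve ties at the threshold to hit the count exactly
    if (sum(ctv) > n_ctv) {
      idx <- which(m_ctv == thr_ctv)
      drop <- idx[seq_len(sum(ctv) - n_ctv)]
      ctv[drop] <- FALSE
    }

    # Chiasm: small ellipsoid (wide in x, thin in z) whose center slides
    # along an anterosuperior axis until the requested overlap with the CTV
    # is achieved to within one voxel.
    ch_asp <- c(2.6, 1.1, 0.85)
    s_ch <- (spec$chiasm_volume_cm3 * 1000 / (4 / 3 * pi * prod(ch_asp)))^(1 / 3)
    ch_semi <- s_ch * ch_asp
    n_ch <- max(1L, round(spec$chiasm_volume_cm3 / vol_vox_cm3))
    ch_dir <- c(0, 0.85, 0.527)
    ch_jit <- jit() * 0.5
    chiasm_at <- function(t) {
      cen <- ctv_c + t * ch_dir + ch_jit
      m <- ((X - cen[1]) / ch_semi[1])^2 + ((Y - cen[2]) / ch_semi[2])^2 +
        ((Z - cen[3]) / ch_semi[3])^2
      m[!external] <- Inf
      thr <- sort.int(as.vector(m), partial = n_ch)[n_ch]
      msk <- m <= thr
      if (sum(msk) > n_ch) {
        idx <- which(m == thr)
        msk[idx[seq_len(sum(msk) - n_ch)]] <- FALSE
      }
      list(mask = msk, center = cen)
    }
    n_target <- round(spec$chiasm_overlap_fraction * n_ch)
    t_lo <- 0
    t_hi <- max(ctv_semi) + max(ch_semi) + 10
    ch <- chiasm_at(t_lo)
    if (sum(ch$mask & ctv) > n_target) {
      for (it in 1:60) {
        t_mid <- (t_lo + t_hi) / 2
        ch_mid <- chiasm_at(t_mid)
        ov <- sum(ch_mid$mask & ctv)
        if (abs(ov - n_target) <= 1) {
          ch <- ch_mid
          break
        }
        if (ov > n_target) t_lo <- t_mid else t_hi <- t_mid
        ch <- ch_mid
        if (t_hi - t_lo < 1e-8) break
      }
    }
    chiasm <- ch$mask
    ch_c <- ch$center

    # Brainstem: vertical elliptic cylinder posterior to the CTV at the
    # requested gap (0 = abutting), measured at the CTV midplane.
    y_post <- ctv_c[2] - ctv_semi[2]
    bs_c2 <- c(ctv_c[1] + jit()[1] * 0.5,
               y_post - spec$brainstem_gap_mm - g$brainstem_semi2d[2])
    brainstem <- (((X - bs_c2[1]) / g$brainstem_semi2d[1])^2 +
                    ((Y - bs_c2[2]) / g$brainstem_semi2d[2])^2 <= 1) &
      Z >= g$brainstem_z[1] & Z <= g$brainstem_z[2] & external

    # Optic nerves: capsule segments from the lateral tips of the chiasm
    # running anterolaterally toward the orbits.
    nerve_mask <- function(side) {
      p0 <- ch_c + c(side * ch_semi[1] * 0.85, 0, 0)
      d <- c(side * 0.62, 0.75, -0.22)
      d <- d / sqrt(sum(d^2))
      p1 <- p0 + d * g$nerve_length
      # distance from voxel centers to segment p0-p1
      vx <- X - p0[1]; vy <- Y - p0[2]; vz <- Z - p0[3]
      tt <- (vx * (p1[1] - p0[1]) + vy * (p1[2] - p0[2]) + vz * (p1[3] - p0[3])) /
        sum((p1 - p0)^2)
      tt <- pmin(pmax(tt, 0), 1)
      dx <- vx - tt * (p1[1] - p0[1])
      dy <- vy - tt * (p1[2] - p0[2])
      dz <- vz - tt * (p1[3] - p0[3])
      r_eff <- max(g$nerve_radius, 0.62 * max(vox))
      (dx^2 + dy^2 + dz^2 <= r_eff^2) & external
    }
    nerve_L <- nerve_mask(+1)
    nerve_R <- nerve_mask(-1)

    density <- array(0, dim3)
    density[external] <- 1
    if (spec$bone_shell) {
      inner <- in_ellipsoid(g$external_c, g$external_semi * 0.94)
      density[external & !inner] <- 1.6
    }

    ph <- structure(list(
      dim = dim3,
      voxel_mm = vox,
      origin_mm = origin,
      density = density,
      structures = list(
        CTV = ctv, brainstem = brainstem, optic_chiasm = chiasm,
        optic_nerve_L = nerve_L, optic_nerve_R = nerve_R,
        brain = brain, external = external
      ),
      patient_class = spec$patient_class,
      uniform_density = !spec$bone_shell,
      shapes = list(
        external = list(center = g$external_c, semi = g$external_semi),
        brain = list(center = g$brain_c, semi = g$brain_semi),
        ctv = list(center = ctv_c, semi = ctv_semi * sqrt(thr_ctv)),
        chiasm = list(center = ch_c, semi = ch_semi)
      ),
      spec = spec
    ), class = "phantom")
    validate_phantom(ph)
    ph
  })
}

#' Validate phantom invariants
#'
#' Checks mask shapes, required structure names, containment of the CTV and
#' all organs at risk in the external contour, and positive voxel volume.
#' Called by [build_phantom()]; exported for externally supplied phantoms.
#'
#' @param ph A `phantom`.
#' @return `ph`, invisibly. Errors if an invariant is violated.
#' @export
validate_phantom <- function(ph) {
  required <- c("CTV", "brainstem", "optic_chiasm", "optic_nerve_L",
                "optic_nerve_R", "brain", "external")
  missing <- setdiff(required, names(ph$structures))
  if (length(missing)) {
    abort(paste0("phantom is missing structures: ", paste(missing, collapse = ", ")))
  }
  for (nm in names(ph$structures)) {
    if (!identical(dim(ph$structures[[nm]]), ph$dim)) {
      abort(paste0("mask '", nm, "' does not match the grid shape"))
    }
  }
  if (!all(ph$voxel_mm > 0)) abort("voxel dimensions must be positive")
  ext <- ph$structures$external
  for (nm in setdiff(required, "external")) {
    if (any(ph$structures[[nm]] & !ext)) {
      abort(paste0("structure '", nm, "' extends outside the external contour"))
    }
  }
  invisible(ph)
}

#' Structure volumes of a phantom
#'
#' @param ph A `phantom`.
#' @return A tibble with `structure`, `n_voxels` and `volume_cm3`
#'   (voxel count times voxel volume).
#' @export
structure_volumes <- function(ph) {
  vv <- prod(ph$voxel_mm) / 1000
  tibble(
    structure = names(ph$structures),
    n_voxels = vapply(ph$structures, sum, integer(1), USE.NAMES = FALSE),
    volume_cm3 = .data$n_voxels * vv
  )
}

#' World coordinates of all voxel centers
#'
#' @param ph A `phantom`.
#' @return An `n x 3` matrix of mm coordinates (x, y, z), in array order.
#' @keywords internal
voxel_centers <- function(ph) {
  ax <- lapply(1:3, function(i) ph$origin_mm[i] + (seq_len(ph$dim[i]) - 1) * ph$voxel_mm[i])
  cbind(
    rep(ax[[1]], times = ph$dim[2] * ph$dim[3]),
    rep(rep(ax[[2]], each = ph$dim[1]), times = ph$dim[3]),
    rep(ax[[3]], each = ph$dim[1] * ph$dim[2])
  )
}

#' Generate a cohort of jittered phantoms
#'
#' Emulates a study cohort by jittering the geometric parameters of a base
#' spec: CTV volume (log-normal, sd 0.15), chiasm overlap fraction (normal,
#' sd 0.08, clamped to `[0.45, 0.95]`), brainstem gap (half the cohort
#' abutting at 0 mm, otherwise uniform on 0-1.5 mm) and global head scale
#' (uniform 0.96-1.04). Deterministic under `seed`.
#'
#' @param n Number of phantoms.
#' @param base_spec A [phantom_spec()] supplying defaults; its
#'   `patient_class` is overridden per phantom.
#' @param seed Integer seed for the cohort (per-phantom seeds are derived).
#' @param adult_fraction Fraction of adult phantoms (default 0.6: a 6/4
#'   adult/pediatric split at `n = 10`).
#' @return A list of `phantom` objects; attribute `specs` carries the
#'   jittered specs.
#' @export
sample_cohort <- function(n, base_spec = phantom_spec(), seed = 1L,
                          adult_fraction = 0.6) {
  stopifnot(n >= 1)
  n_adult <- round(adult_fraction * n)
  classes <- rep(c("adult", "pediatric"), c(n_adult, n - n_adult))
  specs <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n), function(i) {
      cls <- classes[i]
      base_vol <- if (cls == "adult") 30 else 18
      sp <- base_spec
      sp$patient_class <- cls
      sp$random_seed <- as.integer(seed) * 1000L + i
      sp$target_volume_cm3 <- exp(rnorm(1, log(base_vol), 0.15))
      sp$chiasm_overlap_fraction <- min(max(rnorm(1, 0.7, 0.08), 0.45), 0.95)
      sp$brainstem_gap_mm <- if (runif(1) < 0.5) 0 else runif(1, 0, 1.5)
      sp$head_scale <- runif(1, 0.96, 1.04)
      sp$chiasm_volume_cm3 <- if (cls == "adult") 0.9 else 0.7
      sp
    })
  })
  phantoms <- lapply(specs, build_phantom)
  attr(phantoms, "specs") <- specs
  phantoms
}

#' Prescription presets
#'
#' Total prescription, fractionation and per-fraction dose for the two
#' patient classes: adult chondrosarcoma/chordoma 65.13 Gy(RBE) in 39
#' fractions and pediatric craniopharyngioma 50.4 Gy(RBE) in 28 fractions.
#'
#' @param patient_class `"adult"` or `"pediatric"`.
#' @return A one-row tibble with `patient_class`, `total_gy_rbe`,
#'   `n_fractions` and `dose_per_fraction_gy_rbe`.
#' @export
prescription <- function(patient_class = c("adult", "pediatric")) {
  patient_class <- match.arg(patient_class)
  total <- if (patient_class == "adult") 65.13 else 50.4
  nfx <- if (patient_class == "adult") 39L else 28L
  tibble(
    patient_class = patient_class,
    total_gy_rbe = total,
    n_fractions = nfx,
    dose_per_fraction_gy_rbe = total / nfx
  )
}

#' @export
print.phantom <- function(x, ...) {
  cat("<phantom> ", x$patient_class,
      sprintf(" | grid %s @ %s mm\n", paste(x$dim, collapse = "x"),
              paste(signif(x$voxel_mm, 3), collapse = "x")))
  print(structure_volumes(x), n = Inf)
  invisible(x)
}

#' Write a phantom to disk
#'
#' Serializes the density and a structure label volume as NIfTI files plus
#' a JSON sidecar (voxel size, patient class, structure label map, analytic
#' shape parameters and the generating spec).
#'
#' @param ph A `phantom`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(ph, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(
    RNifti::asNifti(ph$density, pixdim = ph$voxel_mm),
    file.path(dir, "density.nii.gz")
  )
  for (nm in names(ph$structures)) {
    RNifti::writeNifti(
      RNifti::asNifti(array(as.integer(ph$structures[[nm]]), ph$dim),
                      pixdim = ph$voxel_mm),
      file.path(dir, paste0("mask_", nm, ".nii.gz"))
    )
  }
  side <- list(
    voxel_mm = ph$voxel_mm, origin_mm = ph$origin_mm, dim = ph$dim,
    patient_class = ph$patient_class, uniform_density = ph$uniform_density,
    structures = names(ph$structures), shapes = ph$shapes,
    spec = unclass(ph$spec)
  )
  jsonlite::write_json(side, file.path(dir, "phantom.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a phantom written by [write_phantom()]
#'
#' @param dir Directory containing `density.nii.gz`, `mask_*.nii.gz` and
#'   `phantom.json`.
#' @return A `phantom`.
#' @export
read_phantom <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "phantom.json"), simplifyVector = TRUE)
  dens <- array(as.numeric(RNifti::readNifti(file.path(dir, "density.nii.gz"))),
                side$dim)
  structs <- lapply(side$structures, function(nm) {
    array(as.numeric(RNifti::readNifti(file.path(dir, paste0("mask_", nm, ".nii.gz")))) > 0.5,
          side$dim)
  })
  names(structs) <- side$structures
  shapes <- side$shapes
  if (!is.null(shapes)) {
    shapes <- lapply(shapes, function(s) lapply(s, as.numeric))
  }
  ph <- structure(list(
    dim = as.integer(side$dim), voxel_mm = side$voxel_mm,
    origin_mm = side$origin_mm, density = dens, structures = structs,
    patient_class = side$patient_class,
    uniform_density = isTRUE(side$uniform_density),
    shapes = shapes, spec = side$spec
  ), class = "phantom")
  validate_phantom(ph)
  ph
}
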