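#' Photon arc surrogate specification
#'
#' A simplified rotational photon comparator: a single coplanar arc of
#' equispaced parallel beams with apertures conformal to the PTV
#' projection and exponentially attenuated fluence. It reproduces the
#' characteristic low-dose photon bath of arc therapy so that
#' modality-comparison metrics are exercisable; it is a fixed-form
#' surrogate, not a model of clinically optimized VMAT.
#'
#' @param n_angles Number of equispaced coplanar beams over 360 degrees
#'   (>= 8; default 72).
#' @param mu_per_cm Linear attenuation coefficient per cm (default 0.05,
#'   6 MV-like).
#' @param ptv_margin_mm Uniform CTV-to-PTV margin in mm (default 3).
#' @param penumbra_sigma_mm Aperture penumbra sigma in mm.
#' @return An object of class `arc_spec`.
#' @export
arc_spec <- function(n_angles = 72, mu_per_cm = 0.05, ptv_margin_mm = 3,
                     penumbra_sigma_mm = 4) {
  stopifnot(n_angles >= 8, mu_per_cm > 0, ptv_margin_mm >= 0)
  structure(list(n_angles = as.integer(n_angles), mu_per_cm = mu_per_cm,
                 ptv_margin_mm = ptv_margin_mm,
                 penumbra_sigma_mm = penumbra_sigma_mm),
            class = "arc_spec")
}

# PTV mask: analytic CTV ellipsoid grown by the margin when shape
# parameters are available, otherwise a center-distance dilation.
ptv_mask <- function(ph, margin_mm) {
  if (!is.null(ph$shapes$ctv)) {
    cen <- ph$shapes$ctv$center
    semi <- ph$shapes$ctv$semi + margin_mm
    ctr <- voxel_centers(ph)
    m <- ((ctr[, 1] - cen[1]) / semi[1])^2 + ((ctr[, 2] - cen[2]) / semi[2])^2 +
      ((ctr[, 3] - cen[3]) / semi[3])^2
    return(array(m <= 1, ph$dim) & ph$structures$external)
  }
  ctv <- ph$structures$CTV
  rad <- ceiling(margin_mm / ph$voxel_mm)
  out <- ctv
  for (di in -rad[1]:rad[1]) for (dj in -rad[2]:rad[2]) for (dk in -rad[3]:rad[3]) {
    if (sum((c(di, dj, dk) * ph$voxel_mm)^2) > margin_mm^2) next
    sh <- ctv
    out <- out | shift_array(sh, c(di, dj, dk))
  }
  out & ph$structures$external
}

shift_array <- function(a, by) {
  d <- dim(a)
  out <- array(FALSE, d)
  src <- lapply(1:3, function(i) {
    max(1, 1 - by[i]):min(d[i], d[i] - by[i])
  })
  dst <- lapply(1:3, function(i) src[[i]] + by[i])
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Compute the photon-arc surrogate dose
#'
#' Sums exponentially attenuated, PTV-conformal parallel beams over the
#' arc and normalizes the result so that the median PTV dose equals the
#' total prescription.
#'
#' @param ph A `phantom`.
#' @param presc Prescription row ([prescription()]); defaults to the
#'   phantom's class.
#' @param arc An [arc_spec()].
#' @return A list of class `photon_plan` with `dose` (a `dose_grid`, Gy),
#'   `ptv` (logical mask), `arc` and `prescription`.
#' @export
plan_arc <- function(ph, presc = NULL, arc = arc_spec()) {
  stopifnot(inherits(ph, "phantom"), inherits(arc, "arc_spec"))
  if (is.null(presc)) presc <- prescription(ph$patient_class)
  ptv <- ptv_mask(ph, arc$ptv_margin_mm)
  if (!any(ptv)) abort("PTV is empty")
  if (any(ptv & !ph$structures$external)) {
    abort("PTV extends outside the external contour")
  }
  centers <- voxel_centers(ph)
  iso <- colMeans(centers[as.vector(ptv), , drop = FALSE])
  raw <- numeric(prod(ph$dim))
  for (a in seq_len(arc$n_angles)) {
    ang <- 360 * (a - 1) / arc$n_angles
    basis <- beam_basis(ang, 0)
    depth <- water_depth(ph, basis$u, centers)
    ap <- make_aperture(ph, basis, iso, ptv, margin_mm = 0,
                        sigma_mm = arc$penumbra_sigma_mm, centers)
    flu <- aperture_fluence(ap, basis, iso, centers)
    act <- which(is.finite(depth) & flu > 1e-4)
    raw[act] <- raw[act] + flu[act] * exp(-arc$mu_per_cm * depth[act] / 10)
  }
  norm <- presc$total_gy_rbe / median(raw[as.vector(ptv)])
  structure(list(
    dose = dose_grid(array(norm * raw, ph$dim), "Gy", ph,
                     meta = list(modality = "photon_surrogate")),
    ptv = ptv, arc = arc, prescription = presc
  ), class = "photon_plan")
}

#' @export
print.photon_plan <- function(x, ...) {
  cat(sprintf("<photon_plan> arc surrogate, %d angles, mu %.3f /cm, PTV %d voxels\n",
              x$arc$n_angles, x$arc$mu_per_cm, sum(x$ptv)))
  invisible(x)
}
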