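# Beam geometry: parallel-beam fields, water-equivalent depth and
# conformal apertures with Gaussian penumbra.

#' Proton field specification
#'
#' Angles follow a simple documented convention: the gantry angle is
#' measured in the axial plane from the anterior direction (clockwise seen
#' from superior) and `elevation_deg` tilts the source out of the axial
#' plane (positive = source superior). The beam is a parallel beam aimed
#' at the isocenter; the spread-out Bragg peak (SOBP) range and modulation
#' are auto-fitted to the CTV projection of each field unless given.
#'
#' @param gantry_deg Gantry angle in degrees.
#' @param elevation_deg Source elevation in degrees (couch-equivalent tilt).
#' @param weight Relative fluence weight (>= 0).
#' @param lateral_sigma_mm Gaussian penumbra sigma in mm.
#' @param aperture_margin_mm Lateral aperture margin beyond the CTV
#'   projection in mm.
#' @param sobp_range_cm Optional fixed SOBP distal range (water-equivalent
#'   cm); `NA` = auto-fit with distal margin 3.5 percent of range + 1 mm.
#' @param modulation_cm Optional fixed SOBP modulation width; `NA` = auto.
#' @return A one-row tibble.
#' @export
beam_spec <- function(gantry_deg, elevation_deg = 0, weight = 1,
                      lateral_sigma_mm = 5, aperture_margin_mm = 6,
                      sobp_range_cm = NA_real_, modulation_cm = NA_real_) {
  stopifnot(weight >= 0, lateral_sigma_mm > 0)
  if (!is.na(sobp_range_cm) && !is.na(modulation_cm)) {
    stopifnot(sobp_range_cm > modulation_cm, modulation_cm >= 0)
  }
  tibble(
    gantry_deg = gantry_deg, elevation_deg = elevation_deg, weight = weight,
    lateral_sigma_mm = lateral_sigma_mm,
    aperture_margin_mm = aperture_margin_mm,
    sobp_range_cm = sobp_range_cm, modulation_cm = modulation_cm
  )
}

#' Default 4-field star beam arrangement
#'
#' Two superior-lateral fields and two inferior-anterior-lateral fields,
#' the latter approximately tangential to the optic structures. The exact
#' clinical gantry/couch angles for this site are center-specific; these
#' defaults reproduce the star topology (opposed-oblique pairs crossing in
#' the target) rather than any particular machine configuration.
#'
#' @param lateral_sigma_mm Penumbra sigma passed to every field.
#' @return A four-row beam tibble.
#' @export
beam_star <- function(lateral_sigma_mm = 5) {
  bind_rows(
    beam_spec(100, 35, lateral_sigma_mm = lateral_sigma_mm),
    beam_spec(260, 35, lateral_sigma_mm = lateral_sigma_mm),
    beam_spec(40, -15, lateral_sigma_mm = lateral_sigma_mm),
    beam_spec(320, -15, lateral_sigma_mm = lateral_sigma_mm)
  )
}

# Unit propagation direction and a lateral orthonormal basis for a field.
beam_basis <- function(gantry_deg, elevation_deg) {
  g <- gantry_deg * pi / 180
  e <- elevation_deg * pi / 180
  src <- c(sin(g) * cos(e), cos(g) * cos(e), sin(e))
  u <- -src
  ref <- if (abs(u[3]) > 0.95) c(1, 0, 0) else c(0, 0, 1)
  e1 <- c(u[2] * ref[3] - u[3] * ref[2],
          u[3] * ref[1] - u[1] * ref[3],
          u[1] * ref[2] - u[2] * ref[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  list(u = u, e1 = e1, e2 = e2)
}

#' Water-equivalent depth of every voxel along a beam direction
#'
#' For uniform-density phantoms with an analytic external ellipsoid the
#' entry point is solved in closed form; otherwise the density is
#' integrated by ray stepping at half-voxel resolution.
#'
#' @param ph A `phantom`.
#' @param u Unit propagation direction (length-3).
#' @param centers Optional precomputed [voxel_centers()] matrix.
#' @return Numeric vector (length = number of voxels, array order) of
#'   water-equivalent depth in mm; `NA` outside the external contour.
#' @export
water_depth <- function(ph, u, centers = NULL) {
  if (is.null(centers)) centers <- voxel_centers(ph)
  ext <- as.vector(ph$structures$external)
  out <- rep(NA_real_, nrow(centers))
  if (isTRUE(ph$uniform_density) && !is.null(ph$shapes$external)) {
    cen <- ph$shapes$external$center
    semi <- ph$shapes$external$semi
    y1 <- (centers[ext, 1] - cen[1]) / semi[1]
    y2 <- (centers[ext, 2] - cen[2]) / semi[2]
    y3 <- (centers[ext, 3] - cen[3]) / semi[3]
    v <- u / semi
    yv <- y1 * v[1] + y2 * v[2] + y3 * v[3]
    yy <- y1^2 + y2^2 + y3^2
    disc <- pmax(yv^2 - sum(v^2) * (yy - 1), 0)
    out[ext] <- (yv + sqrt(disc)) / sum(v^2)
    return(out)
  }
  # generic density-weighted ray stepping (nearest-voxel sampling)
  h <- min(ph$voxel_mm) / 2
  n_steps <- ceiling(sqrt(sum((ph$dim * ph$voxel_mm)^2)) / h)
  idx <- which(ext)
  pos <- centers[idx, , drop = FALSE]
  acc <- numeric(length(idx))
  dens <- ph$density
  d1 <- ph$dim[1]; d12 <- ph$dim[1] * ph$dim[2]
  for (m in seq_len(n_steps)) {
    px <- pos[, 1] - (m - 0.5) * h * u[1]
    py <- pos[, 2] - (m - 0.5) * h * u[2]
    pz <- pos[, 3] - (m - 0.5) * h * u[3]
    i <- round((px - ph$origin_mm[1]) / ph$voxel_mm[1]) + 1
    j <- round((py - ph$origin_mm[2]) / ph$voxel_mm[2]) + 1
    k <- round((pz - ph$origin_mm[3]) / ph$voxel_mm[3]) + 1
    ok <- i >= 1 & i <= ph$dim[1] & j >= 1 & j <= ph$dim[2] &
      k >= 1 & k <= ph$dim[3]
    if (!any(ok)) break
    lin <- (i[ok] - 1) + (j[ok] - 1) * d1 + (k[ok] - 1) * d12 + 1
    acc[ok] <- acc[ok] + dens[lin] * h
  }
  out[idx] <- acc
  out
}

# Build a smoothed conformal aperture for one field: the target mask is
# projected onto the lateral plane, dilated by the aperture margin (plus a
# half-voxel rasterization allowance) and blurred with the penumbra sigma.
# Returned as a 2D fluence map evaluable at lateral coordinates.
make_aperture <- function(ph, basis, iso, target_mask, margin_mm, sigma_mm,
                          centers = NULL) {
  if (is.null(centers)) centers <- voxel_centers(ph)
  tgt <- which(as.vector(target_mask))
  if (!length(tgt)) abort("aperture target mask is empty")
  t1 <- (centers[tgt, 1] - iso[1]) * basis$e1[1] +
    (centers[tgt, 2] - iso[2]) * basis$e1[2] +
    (centers[tgt, 3] - iso[3]) * basis$e1[3]
  t2 <- (centers[tgt, 1] - iso[1]) * basis$e2[1] +
    (centers[tgt, 2] - iso[2]) * basis$e2[2] +
    (centers[tgt, 3] - iso[3]) * basis$e2[3]
  h <- min(2, min(ph$voxel_mm))
  pad <- margin_mm + 4 * sigma_mm + 2 * h
  o1 <- min(t1) - pad; o2 <- min(t2) - pad
  n1 <- ceiling((max(t1) + pad - o1) / h) + 1
  n2 <- ceiling((max(t2) + pad - o2) / h) + 1
  occ <- matrix(0, n1, n2)
  occ[cbind(pmin(pmax(round((t1 - o1) / h) + 1, 1), n1),
            pmin(pmax(round((t2 - o2) / h) + 1, 1), n2))] <- 1
  # binary dilation by margin + half-voxel diagonal allowance
  rad <- margin_mm + 0.5 * sqrt(2) * max(ph$voxel_mm)
  rc <- ceiling(rad / h)
  dil <- occ
  for (di in -rc:rc) for (dj in -rc:rc) {
    if (di^2 + dj^2 > (rad / h)^2 || (di == 0 && dj == 0)) next
    si <- max(1, 1 + di):min(n1, n1 + di)
    ti <- si - di
    sj <- max(1, 1 + dj):min(n2, n2 + dj)
    tj <- sj - dj
    dil[ti, tj] <- pmax(dil[ti, tj], occ[si, sj])
  }
  # separable Gaussian blur (penumbra)
  gk <- function(n) {
    half <- ceiling(3 * sigma_mm / h)
    kn <- dnorm((-half):half, sd = sigma_mm / h)
    kn <- kn / sum(kn)
    M <- matrix(0, n, n)
    for (d in (-half):half) {
      ii <- max(1, 1 + d):min(n, n + d)
      M[cbind(ii - d, ii)] <- kn[d + half + 1]
    }
    # renormalize rows near the border
    M / rowSums(M)
  }
  flu <- gk(n1) %*% dil %*% t(gk(n2))
  list(map = flu, o1 = o1, o2 = o2, h = h, n1 = n1, n2 = n2)
}

# Evaluate an aperture map at world positions (bilinear), optionally with
# the beam geometry translated by shift_mm (a setup-error realization).
aperture_fluence <- function(ap, basis, iso, centers, shift_mm = c(0, 0, 0)) {
  px <- centers[, 1] - iso[1] - shift_mm[1]
  py <- centers[, 2] - iso[2] - shift_mm[2]
  pz <- centers[, 3] - iso[3] - shift_mm[3]
  p1 <- px * basis$e1[1] + py * basis$e1[2] + pz * basis$e1[3]
  p2 <- px * basis$e2[1] + py * basis$e2[2] + pz * basis$e2[3]
  f1 <- (p1 - ap$o1) / ap$h + 1
  f2 <- (p2 - ap$o2) / ap$h + 1
  i0 <- floor(f1); j0 <- floor(f2)
  wi <- f1 - i0; wj <- f2 - j0
  out <- numeric(length(p1))
  ok <- i0 >= 1 & i0 < ap$n1 & j0 >= 1 & j0 < ap$n2
  if (any(ok)) {
    i0k <- i0[ok]; j0k <- j0[ok]; wik <- wi[ok]; wjk <- wj[ok]
    m <- ap$map
    v00 <- m[cbind(i0k, j0k)]
    v10 <- m[cbind(i0k + 1, j0k)]
    v01 <- m[cbind(i0k, j0k + 1)]
    v11 <- m[cbind(i0k + 1, j0k + 1)]
    out[ok] <- v00 * (1 - wik) * (1 - wjk) + v10 * wik * (1 - wjk) +
      v01 * (1 - wik) * wjk + v11 * wik * wjk
  }
  out
}
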