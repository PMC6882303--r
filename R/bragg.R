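# Analytical proton depth-dose and LET model.
#
# Protons in water follow a power-law range-energy relation R = alpha * E^p
# (alpha = 0.0022 cm MeV^-p, p = 1.77), so the stopping power at residual
# range r is S(r) = r^(1/p - 1) / (p alpha^(1/p)) (MeV/cm). Range straggling
# is modeled as a Gaussian spread of the end-of-range. The depth-dose of a
# pristine peak and its dose-averaged LET then depend only on the *residual
# range* u = range - depth:
#   D(u)     =  E[ S(R' - z) ]         over  R' ~ N(range, sigma)
#   LET_d(u) =  E[ S^2 ] / E[ S ]      (dose-averaged over the spectrum)
# Both expectations have integrable power singularities at r = 0 which are
# removed exactly by the substitutions r = t^p and r = t^(p/(2-p)).

.bragg_alpha <- 0.0022
.bragg_p <- 1.77

# Depth-dose and LET profile as a function of residual range u (cm).
# Returns u grid, unnormalized dose, LET_d in keV/um (capped), and the
# residual range u_peak at which the dose maximum occurs.
bragg_profile <- function(sigma_cm, u_max, du = 0.02, n_quad = 400,
                          let_cap = 20) {
  p <- .bragg_p
  a <- .bragg_alpha
  u <- seq(-(6 * sigma_cm + 0.5), u_max, by = du)
  dose <- numeric(length(u))
  letd <- rep(let_cap, length(u))
  q <- p / (2 - p)
  for (i in seq_along(u)) {
    r_up <- u[i] + 6 * sigma_cm
    if (r_up <= 0) next
    t_up <- r_up^(1 / p)
    tg <- (seq_len(n_quad) - 0.5) * (t_up / n_quad)
    s1 <- sum(dnorm(tg^p, u[i], sigma_cm)) * (t_up / n_quad) / a^(1 / p)
    v_up <- r_up^(1 / q)
    vg <- (seq_len(n_quad) - 0.5) * (v_up / n_quad)
    s2 <- sum(dnorm(vg^q, u[i], sigma_cm)) * (v_up / n_quad) *
      (p / (2 - p)) / (p^2 * a^(2 / p))
    dose[i] <- s1
    if (s1 > 0) letd[i] <- min(s2 / s1 * 0.1, let_cap)  # MeV/cm -> keV/um
  }
  list(u = u, dose = dose, let = letd, u_peak = u[which.max(dose)],
       sigma_cm = sigma_cm, let_cap = let_cap)
}

# Evaluate a profile at arbitrary residual ranges (linear interpolation;
# zero dose beyond the falloff, capped LET there).
profile_dose <- function(prof, u) {
  approx(prof$u, prof$dose, xout = u, rule = 2, yleft = 0)$y *
    (u >= min(prof$u))
}
profile_let <- function(prof, u) {
  out <- approx(prof$u, prof$let, xout = u, rule = 2)$y
  out[u < min(prof$u)] <- prof$let_cap
  out
}

#' Pristine Bragg curve with dose-averaged LET
#'
#' Computes the depth-dose curve and depth-LET curve of a single
#' (pristine) proton Bragg peak in water from a power-law range-energy
#' stopping model with Gaussian range straggling. The curve is
#' parameterized so that the dose maximum sits at `range_cm`; dose is
#' normalized to a peak value of 1, LET is the dose-averaged LET in
#' keV/um, capped at `let_cap` in the falloff tail.
#'
#' @param range_cm Peak depth in water-equivalent cm, in `[1, 35]`.
#' @param depth_step_mm Depth grid spacing in mm (default 0.5).
#' @param sigma_cm Range-straggling standard deviation in cm; default
#'   1.2 percent of `range_cm`.
#' @param let_cap LET cap in keV/um applied in the distal tail where the
#'   dose vanishes (default 20).
#' @return An object of class `pristine_curve`: a list with `range_cm`,
#'   `sigma_cm`, `depth_cm`, `dose` (peak-normalized) and `let_kev_um`.
#' @examples
#' pc <- pristine_curve(15)
#' pc$depth_cm[which.max(pc$dose)]  # ~15
#' @export
pristine_curve <- function(range_cm, depth_step_mm = 0.5, sigma_cm = NULL,
                           let_cap = 20) {
  if (range_cm < 1 || range_cm > 35) {
    abort("range_cm must be between 1 and 35 cm")
  }
  stopifnot(depth_step_mm > 0)
  if (is.null(sigma_cm)) sigma_cm <- 0.012 * range_cm
  prof <- bragg_profile(sigma_cm, u_max = range_cm + 6 * sigma_cm + 0.5,
                        let_cap = let_cap)
  z <- seq(0, range_cm + 3, by = depth_step_mm / 10)
  u <- range_cm - z + prof$u_peak   # peak lands at z = range_cm
  dose <- profile_dose(prof, u)
  structure(list(
    range_cm = range_cm, sigma_cm = sigma_cm,
    depth_cm = z, dose = dose / max(dose),
    let_kev_um = profile_let(prof, u)
  ), class = "pristine_curve")
}

#' @export
print.pristine_curve <- function(x, ...) {
  cat(sprintf("<pristine_curve> range %.2f cm, straggling sigma %.3f cm, %d depth points\n",
              x$range_cm, x$sigma_cm, length(x$depth_cm)))
  invisible(x)
}

#' Spread-out Bragg peak weights
#'
#' Fits non-negative weights for a stack of pulled-back pristine peaks so
#' that the composite depth dose is flat over the modulation plateau
#' `[range - modulation, range]`. Weights are obtained by non-negative
#' least squares against a unit plateau on a fine depth grid. All pulled
#' back peaks share the straggling width of the deepest peak (energy
#' degradation preserves the absolute spread of the field).
#'
#' @param range_cm Distal peak depth (cm).
#' @param modulation_cm SOBP width (cm); `0` with `n_peaks = 1` gives the
#'   degenerate single-peak case.
#' @param n_peaks Number of pullback peaks; default spaces peaks one
#'   straggling width apart (`ceiling(modulation/sigma) + 1`).
#' @return An object of class `sobp_fit`: list with `range_cm`,
#'   `modulation_cm`, `sigma_cm`, `ranges_cm` (distal first), `weights`
#'   (non-negative, distal first), and `flatness` (max deviation from the
#'   plateau mean, as a fraction). A warning is raised if the plateau is
#'   not flat within 2 percent.
#' @examples
#' fit <- sobp_weights(12, 4, n_peaks = 12)
#' fit$flatness  # < 0.02
#' @export
sobp_weights <- function(range_cm, modulation_cm, n_peaks = NULL) {
  stopifnot(range_cm > modulation_cm, modulation_cm >= 0)
  sigma <- 0.012 * range_cm
  if (modulation_cm == 0) {
    if (is.null(n_peaks)) n_peaks <- 1L
    if (n_peaks == 1) {
      return(structure(list(
        range_cm = range_cm, modulation_cm = 0, sigma_cm = sigma,
        ranges_cm = range_cm, weights = 1, flatness = 0
      ), class = "sobp_fit"))
    }
  }
  if (is.null(n_peaks)) n_peaks <- max(2L, ceiling(modulation_cm / sigma) + 1L)
  if (n_peaks < 2) abort("n_peaks must be >= 2 for a nonzero modulation")
  spacing <- modulation_cm / (n_peaks - 1)
  ranges <- range_cm - (seq_len(n_peaks) - 1) * spacing
  if (min(ranges) <= 0) abort("pullback peaks extend to non-positive range")

  prof <- bragg_profile(sigma, u_max = range_cm + 6 * sigma + 0.5)
  pk <- max(prof$dose)
  step <- min(sigma / 3, 0.05)
  zg <- seq(max(0, range_cm - modulation_cm - 1), range_cm + 0.5, by = step)
  A <- vapply(ranges, function(r) {
    profile_dose(prof, r - zg + prof$u_peak) / pk
  }, numeric(length(zg)))
  plateau <- zg >= (range_cm - modulation_cm) & zg <= range_cm
  w <- pracma::lsqnonneg(A[plateau, , drop = FALSE], rep(1, sum(plateau)))$x
  comp <- as.vector(A %*% w)
  pl <- comp[plateau]
  flat <- max(abs(pl - mean(pl))) / mean(pl)
  if (flat > 0.02) {
    warn(sprintf(paste0("SOBP plateau flatness %.2f%% exceeds the 2%% target; ",
                        "increase n_peaks"), 100 * flat))
  }
  structure(list(
    range_cm = range_cm, modulation_cm = modulation_cm, sigma_cm = sigma,
    ranges_cm = ranges, weights = w, flatness = flat
  ), class = "sobp_fit")
}

#' @export
print.sobp_fit <- function(x, ...) {
  cat(sprintf("<sobp_fit> range %.2f cm, modulation %.2f cm, %d peaks, flatness %.2f%%\n",
              x$range_cm, x$modulation_cm, length(x$weights), 100 * x$flatness))
  invisible(x)
}

# Composite SOBP depth curves for one field: dose and dose*LET as a
# function of depth, from a shared residual-range profile.
sobp_depth_curves <- function(fit, depth_cm, prof = NULL) {
  if (is.null(prof)) {
    prof <- bragg_profile(fit$sigma_cm,
                          u_max = max(fit$ranges_cm) + 6 * fit$sigma_cm + 0.5)
  }
  pk <- max(prof$dose)
  dose <- numeric(length(depth_cm))
  dlet <- numeric(length(depth_cm))
  for (k in seq_along(fit$ranges_cm)) {
    u <- fit$ranges_cm[k] - depth_cm + prof$u_peak
    dk <- fit$weights[k] * profile_dose(prof, u) / pk
    dose <- dose + dk
    dlet <- dlet + dk * profile_let(prof, u)
  }
  list(dose = dose, dlet = dlet)
}
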