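# RBE models and fractionation-scheme constraint conversion.

# Published fit coefficients of the McNamara phenomenological RBE model
# (linear-quadratic based, fitted to the pre-2014 in vitro proton RBE
# database). Recorded here for transparency; overridable via arguments.
mcnamara_coefficients <- function() {
  c(p0 = 0.99064, p1 = 0.35605, p2 = 1.1012, p3 = -0.0038703)
}

#' McNamara variable proton RBE
#'
#' Voxelwise phenomenological RBE as a function of the physical proton
#' dose per fraction `D_p`, the dose-averaged LET and the tissue
#' `(alpha/beta)_x` of the reference radiation:
#' \deqn{RBE = \frac{1}{2 D_p}\left(\sqrt{(\alpha/\beta)_x^2 +
#'   4 D_p (\alpha/\beta)_x\, RBE_{max} + 4 D_p^2\, RBE_{min}^2}
#'   - (\alpha/\beta)_x\right)}
#' with \eqn{RBE_{max} = p_0 + p_1\, LET_d / (\alpha/\beta)_x} and
#' \eqn{RBE_{min} = p_2 + p_3 \sqrt{(\alpha/\beta)_x}\, LET_d}. At
#' `D_p = 0` the analytic limit `RBE_max` is returned; `RBE_min` is
#' floored at zero where the linear LET term would make it negative.
#' The model predicts increased RBE for low `(alpha/beta)_x` and high
#' LET_d.
#'
#' @param dose_per_fx Physical proton dose per fraction in Gy (>= 0),
#'   vectorized.
#' @param letd Dose-averaged LET in keV/um (>= 0), vectorized.
#' @param alpha_beta_x Reference-radiation alpha/beta ratio in Gy (> 0).
#' @param coef Named coefficient vector (`p0`, `p1`, `p2`, `p3`).
#' @return RBE values (dimensionless), recycled to the common length.
#' @export
rbe_mcnamara <- function(dose_per_fx, letd, alpha_beta_x,
                         coef = mcnamara_coefficients()) {
  if (any(dose_per_fx < 0, na.rm = TRUE) || any(letd < 0, na.rm = TRUE)) {
    abort("dose and LET must be non-negative")
  }
  if (any(alpha_beta_x <= 0)) abort("(alpha/beta)_x must be positive")
  ab <- alpha_beta_x
  rbe_max <- coef[["p0"]] + coef[["p1"]] * letd / ab
  rbe_min <- pmax(coef[["p2"]] + coef[["p3"]] * sqrt(ab) * letd, 0)
  d <- dose_per_fx
  out <- rbe_max  # analytic limit at D_p = 0
  pos <- d > 0
  if (any(pos)) {
    if (length(ab) == 1) ab <- rep(ab, length(d))
    ab <- rep_len(ab, length(d))
    rmx <- rep_len(rbe_max, length(d))
    rmn <- rep_len(rbe_min, length(d))
    dd <- rep_len(d, length(d))
    out <- rep_len(out, length(d))
    out[pos] <- (sqrt(ab[pos]^2 + 4 * dd[pos] * ab[pos] * rmx[pos] +
                        4 * dd[pos]^2 * rmn[pos]^2) - ab[pos]) / (2 * dd[pos])
  }
  out
}

#' RBE-weighted dose
#'
#' Converts a total physical proton dose grid to RBE-weighted dose, using
#' either the constant clinical RBE of 1.1 or the McNamara variable RBE
#' model evaluated at the per-fraction dose (total / `n_fractions`,
#' uniform fractionation assumed). Voxels excluded from the LET map by
#' its dose threshold fall back to the constant RBE of 1.1.
#'
#' @param dose A `dose_grid` with unit `"Gy"` (total physical dose).
#' @param letd A `dose_grid` with unit `"keV/um"` (ignored for the
#'   constant model).
#' @param model `"constant_1p1"` or `"mcnamara"`.
#' @param alpha_beta_x Scalar `(alpha/beta)_x` in Gy, or a named vector of
#'   per-structure overrides applied on top of a global value given as the
#'   unnamed/`.default` entry (requires `ph`); later entries win where
#'   structures overlap.
#' @param n_fractions Number of fractions.
#' @param ph Phantom (required only for per-structure `alpha_beta_x`).
#' @return A `dose_grid` with unit `"Gy(RBE)"`.
#' @export
rbe_weighted_dose <- function(dose, letd = NULL,
                              model = c("mcnamara", "constant_1p1"),
                              alpha_beta_x = 2, n_fractions = NULL,
                              ph = NULL) {
  model <- match.arg(model)
  if (!identical(dose$unit, "Gy")) {
    abort(sprintf("expected a physical dose grid in 'Gy', got '%s'", dose$unit))
  }
  if (model == "constant_1p1") {
    out <- dose_grid(dose$values * 1.1, "Gy(RBE)",
                     meta = c(dose$meta, list(rbe_model = "constant_1p1")))
    return(out)
  }
  if (is.null(letd) || !identical(letd$unit, "keV/um")) {
    abort("the McNamara model needs a LET grid in 'keV/um'")
  }
  if (is.null(n_fractions)) abort("n_fractions is required for variable RBE")
  ab_label <- paste(names(alpha_beta_x) %||% "", signif(alpha_beta_x, 4),
                    collapse = ",")
  if (length(alpha_beta_x) > 1 || !is.null(names(alpha_beta_x))) {
    if (is.null(ph)) abort("per-structure alpha_beta_x needs the phantom")
    nm <- names(alpha_beta_x)
    global <- if (any(nm == "" | nm == ".default")) {
      alpha_beta_x[[which(nm == "" | nm == ".default")[1]]]
    } else 2
    ab <- array(global, dim(dose$values))
    for (i in seq_along(alpha_beta_x)) {
      if (nm[i] %in% names(ph$structures)) {
        ab[ph$structures[[nm[i]]]] <- alpha_beta_x[[i]]
      }
    }
  } else {
    ab <- alpha_beta_x
  }
  d_fx <- dose$values / n_fractions
  rbe <- rbe_mcnamara(as.vector(d_fx), as.vector(letd$values), as.vector(ab))
  excl <- attr(letd, "excluded")
  if (!is.null(excl)) rbe[as.vector(excl)] <- 1.1
  dose_grid(array(dose$values * rbe, dim(dose$values)), "Gy(RBE)",
            meta = c(dose$meta, list(rbe_model = "mcnamara",
                                     alpha_beta_x = ab_label)))
}

#' Isoeffective dose constraint conversion between fractionation schemes
#'
#' Transfers a total dose constraint `D2` defined for a scheme with dose
#' per fraction `d2` to the scheme with dose per fraction `d1` at equal
#' biologically effective dose (linear-quadratic model):
#' \deqn{D_1 = D_2\,\frac{1 + d_2/(\alpha/\beta)_x}{1 + d_1/(\alpha/\beta)_x}}
#' This is how published constraints expressed as equivalent dose in
#' 2 Gy(RBE) fractions are mapped onto a plan's own fractionation.
#'
#' @param D2 Total constraint dose in the source scheme, Gy(RBE).
#' @param d2 Dose per fraction of the source scheme, Gy(RBE) (e.g. 2).
#' @param d1 Dose per fraction of the target scheme, Gy(RBE) (e.g.
#'   65.13/39 = 1.67 for the adult prescription).
#' @param alpha_beta_x Tissue `(alpha/beta)_x` in Gy (> 0).
#' @return `D1`, the isoeffective total constraint for the target scheme.
#' @examples
#' eqd_convert(60, d2 = 2, d1 = 65.13 / 39, alpha_beta_x = 2)
#' @export
eqd_convert <- function(D2, d2, d1, alpha_beta_x) {
  if (any(alpha_beta_x <= 0)) abort("(alpha/beta)_x must be positive")
  stopifnot(all(D2 > 0), all(d2 > 0), all(d1 > 0))
  D2 * (1 + d2 / alpha_beta_x) / (1 + d1 / alpha_beta_x)
}

#' Convert a table of EQD2-style constraints to a fractionation scheme
#'
#' Applies [eqd_convert()] row-wise to a constraint table with columns
#' `structure`, `limit_eqd2` (total Gy(RBE) at 2 Gy(RBE)/fraction) and
#' `alpha_beta_x`.
#'
#' @param tab Constraint tibble (see `inst/extdata`).
#' @param d1 Target dose per fraction, Gy(RBE).
#' @param d2 Source dose per fraction (default 2).
#' @return The table with an added `limit_converted` column.
#' @export
eqd_convert_table <- function(tab, d1, d2 = 2) {
  mutate(tab, limit_converted = eqd_convert(.data$limit_eqd2, d2 = d2,
                                            d1 = d1,
                                            alpha_beta_x = .data$alpha_beta_x))
}
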