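#' Forward-compute a multi-field proton plan
#'
#' Composes a multi-field IMPT-like plan on a phantom: for every field the
#' SOBP range and modulation are auto-fitted to the water-equivalent depth
#' interval of the CTV along the beam axis (distal/proximal margins of
#' 3.5 percent of range + 1 mm, the clinical range-uncertainty recipe),
#' pullback weights are fitted for a flat plateau, and voxel dose is
#' `field weight x SOBP(depth) x lateral aperture fluence`. The total
#' physical dose is normalized so that the median CTV dose times the
#' planning RBE of 1.1 equals the prescription (plans are optimized under
#' the constant clinical RBE; variable RBE is applied post hoc).
#'
#' @param ph A `phantom`.
#' @param beams Beam tibble from [beam_spec()] / [beam_star()].
#' @param presc Prescription row from [prescription()]; defaults to the
#'   phantom's patient class.
#' @param isocenter Isocenter in mm world coordinates (default the CTV
#'   centroid).
#' @return An object of class `proton_plan`: list with `beams` (fitted
#'   tibble), `dose` (total physical `dose_grid`, Gy), `letd`
#'   (dose-averaged LET `dose_grid`, keV/um, with attribute `excluded`
#'   marking voxels below the LET dose threshold), `norm_factor`,
#'   `prescription`, and per-field geometry for scenario recomputation.
#' @export
plan_proton <- function(ph, beams = beam_star(), presc = NULL,
                        isocenter = NULL) {
  stopifnot(inherits(ph, "phantom"), nrow(beams) >= 1)
  if (is.null(presc)) presc <- prescription(ph$patient_class)
  ctv <- as.vector(ph$structures$CTV)
  centers <- voxel_centers(ph)
  if (is.null(isocenter)) isocenter <- colMeans(centers[ctv, , drop = FALSE])

  fields <- vector("list", nrow(beams))
  raw <- numeric(prod(ph$dim))
  dlet_acc <- numeric(prod(ph$dim))
  beams_out <- beams
  for (f in seq_len(nrow(beams))) {
    b <- beams[f, ]
    basis <- beam_basis(b$gantry_deg, b$elevation_deg)
    depth <- water_depth(ph, basis$u, centers)
    d_ctv <- depth[ctv]
    if (!any(is.finite(d_ctv))) {
      abort(sprintf("field %d (gantry %g) misses the CTV entirely", f, b$gantry_deg))
    }
    d_ctv <- d_ctv[is.finite(d_ctv)] / 10  # mm -> cm
    if (is.na(b$sobp_range_cm)) {
      rng <- (max(d_ctv) + 0.1) / 0.965
      prox <- max(0.965 * min(d_ctv) - 0.1, 0.3)
      mod <- min(rng - prox, rng - 0.3)
    } else {
      rng <- b$sobp_range_cm
      mod <- b$modulation_cm
    }
    fit <- sobp_weights(rng, mod)
    ap <- make_aperture(ph, basis, isocenter, ph$structures$CTV,
                        b$aperture_margin_mm, b$lateral_sigma_mm, centers)
    flu <- aperture_fluence(ap, basis, isocenter, centers)
    act <- which(is.finite(depth) & flu > 1e-4)
    cur <- sobp_depth_curves(fit, depth[act] / 10)
    dose_f <- numeric(length(raw))
    dlet_f <- numeric(length(raw))
    dose_f[act] <- b$weight * flu[act] * cur$dose
    dlet_f[act] <- b$weight * flu[act] * cur$dlet
    raw <- raw + dose_f
    dlet_acc <- dlet_acc + dlet_f
    beams_out$sobp_range_cm[f] <- rng
    beams_out$modulation_cm[f] <- mod
    fields[[f]] <- list(basis = basis, fit = fit, aperture = ap,
                        weight = b$weight)
  }
  norm <- (presc$total_gy_rbe / 1.1) / median(raw[ctv])
  total <- array(norm * raw, ph$dim)

  thr <- 0.005 * max(total)
  excluded <- total < thr
  let_vals <- numeric(length(raw))
  nz <- !as.vector(excluded)
  let_vals[nz] <- dlet_acc[nz] / raw[nz]
  letd <- dose_grid(array(let_vals, ph$dim), "keV/um",
                    meta = list(dose_threshold = thr, model = "analytical_letd"))
  attr(letd, "excluded") <- excluded

  structure(list(
    beams = beams_out,
    fields = fields,
    isocenter = isocenter,
    norm_factor = norm,
    prescription = presc,
    dose = dose_grid(total, "Gy", ph,
                     meta = list(modality = "proton", scenario = "nominal")),
    letd = letd,
    dim = ph$dim
  ), class = "proton_plan")
}

#' @export
print.proton_plan <- function(x, ...) {
  cat(sprintf("<proton_plan> %d fields | prescription %.2f Gy(RBE) / %d fx\n",
              nrow(x$beams), x$prescription$total_gy_rbe,
              x$prescription$n_fractions))
  print(select(x$beams, "gantry_deg", "elevation_deg", "weight",
               "sobp_range_cm", "modulation_cm"))
  invisible(x)
}

#' Dose-averaged LET of a mixture of contributions
#'
#' Voxelwise `LET_d = sum(d_i * L_i) / sum(d_i)` over dose contributions,
#' with the LET set to zero (and flagged excluded) wherever the total dose
#' falls below a fraction of the maximum total dose — the dose threshold
#' used when computing LET maps on plans.
#'
#' @param doses List of numeric vectors/arrays of dose contributions.
#' @param lets List of matching LET contributions (keV/um).
#' @param threshold_frac Exclusion threshold as a fraction of the maximum
#'   total dose (default 0.005, i.e. 0.5 percent).
#' @return Numeric vector/array of dose-averaged LET with attribute
#'   `excluded` (logical).
#' @export
dose_averaged_let <- function(doses, lets, threshold_frac = 0.005) {
  stopifnot(length(doses) == length(lets), length(doses) >= 1)
  tot <- Reduce(`+`, doses)
  num <- Reduce(`+`, Map(`*`, doses, lets))
  thr <- threshold_frac * max(tot)
  excluded <- tot < thr
  out <- num
  out[!excluded] <- num[!excluded] / tot[!excluded]
  out[excluded] <- 0
  attr(out, "excluded") <- excluded
  out
}

#' Recompute a plan's dose under a systematic error scenario
#'
#' Recomputes (never interpolates) the plan dose with the beam geometry
#' rigidly translated by `shift_mm` relative to the patient and every
#' field's SOBP range and modulation depths scaled by `range_scale`.
#' Field weights and the dose normalization factor stay frozen at their
#' nominal values, so errors change the delivered dose rather than being
#' renormalized away.
#'
#' @param plan A `proton_plan`.
#' @param ph The `phantom` the plan was computed on.
#' @param shift_mm Length-3 isocenter shift in mm.
#' @param range_scale Multiplicative water-equivalent range scaling
#'   (e.g. 1.035 for +3.5 percent).
#' @param scenario_id Optional id recorded in the grid metadata.
#' @return A total-physical-dose `dose_grid` (Gy).
#' @export
apply_scenario <- function(plan, ph, shift_mm = c(0, 0, 0), range_scale = 1,
                           scenario_id = NULL) {
  stopifnot(inherits(plan, "proton_plan"), length(shift_mm) == 3,
            range_scale > 0)
  centers <- voxel_centers(ph)
  raw <- numeric(prod(ph$dim))
  any_hit <- FALSE
  for (f in seq_along(plan$fields)) {
    fl <- plan$fields[[f]]
    depth <- water_depth(ph, fl$basis$u, centers)
    fit <- fl$fit
    fit$ranges_cm <- fit$ranges_cm * range_scale
    fit$sigma_cm <- fit$sigma_cm * range_scale
    flu <- aperture_fluence(fl$aperture, fl$basis, plan$isocenter, centers,
                            shift_mm = shift_mm)
    act <- which(is.finite(depth) & flu > 1e-4)
    if (!length(act)) next
    any_hit <- TRUE
    cur <- sobp_depth_curves(fit, depth[act] / 10)
    raw[act] <- raw[act] + fl$weight * flu[act] * cur$dose
  }
  if (!any_hit) abort("shifted beams miss the phantom entirely")
  dose_grid(array(plan$norm_factor * raw, ph$dim), "Gy", ph,
            meta = list(modality = "proton",
                        scenario = scenario_id %||% sprintf(
                          "shift(%g,%g,%g)mm_range%+.1f%%",
                          shift_mm[1], shift_mm[2], shift_mm[3],
                          100 * (range_scale - 1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
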