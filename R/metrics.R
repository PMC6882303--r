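# Dose-volume histograms and clinical dose metrics.

#' Cumulative dose-volume histogram
#'
#' @param grid A `dose_grid`.
#' @param mask Logical 3D mask, or a structure name looked up in `ph`.
#' @param ph Phantom (required if `mask` is a name; also supplies the
#'   voxel volume).
#' @param bin_gy Dose bin width in Gy (default 0.05).
#' @param voxel_cm3 Voxel volume in cm^3; derived from `ph` if given.
#' @return A tibble of class `dvh` with columns `dose` (bin edges from 0),
#'   `volume_frac` (fraction of the structure receiving at least `dose`)
#'   and `volume_cm3`; attributes `structure`, `total_cm3`, `bin_gy`,
#'   `unit`. The curve is monotone non-increasing with
#'   `volume_frac[dose = 0] = 1`.
#' @export
compute_dvh <- function(grid, mask, ph = NULL, bin_gy = 0.05,
                        voxel_cm3 = NULL) {
  name <- NULL
  if (is.character(mask)) {
    if (is.null(ph)) abort("a phantom is needed to look up a structure name")
    name <- mask
    mask <- ph$structures[[mask]]
    if (is.null(mask)) abort(sprintf("structure '%s' not found", name))
  }
  if (!any(mask)) abort("empty structure mask")
  if (is.null(voxel_cm3)) {
    if (is.null(ph)) abort("supply ph or voxel_cm3 for absolute volumes")
    voxel_cm3 <- prod(ph$voxel_mm) / 1000
  }
  d <- grid$values[mask]
  n <- length(d)
  edges <- seq(0, max(d) + bin_gy, by = bin_gy)
  # fraction of voxels with dose >= edge
  cnt <- n - findInterval(edges - 1e-12, sort(d))
  out <- tibble(dose = edges, volume_frac = cnt / n,
                volume_cm3 = cnt * voxel_cm3)
  structure(out, class = c("dvh", class(out)),
            structure_name = name %||% "structure",
            total_cm3 = n * voxel_cm3, bin_gy = bin_gy, unit = grid$unit)
}

#' Minimum dose to the hottest volume (D_V)
#'
#' The minimum dose received by the hottest `volume_cm3` (or
#' `volume_pct`) of the structure — e.g. `D0.1cc` or `D95`. Linear
#' interpolation between DVH bins.
#'
#' @param dvh A `dvh` from [compute_dvh()].
#' @param volume_cm3 Absolute volume in cm^3 (one of the two).
#' @param volume_pct Relative volume in percent of the structure.
#' @return Dose in the grid's unit.
#' @export
dose_at_volume <- function(dvh, volume_cm3 = NULL, volume_pct = NULL) {
  total <- attr(dvh, "total_cm3")
  if (is.null(volume_cm3)) {
    if (is.null(volume_pct)) abort("give volume_cm3 or volume_pct")
    volume_cm3 <- volume_pct / 100 * total
  }
  if (volume_cm3 <= 0 || volume_cm3 > total + 1e-9) {
    abort("requested volume exceeds the structure volume (or is <= 0)")
  }
  v <- dvh$volume_cm3
  d <- dvh$dose
  i <- max(which(v >= volume_cm3))
  if (i == length(v)) return(d[i])
  if (v[i] == v[i + 1]) return(d[i])
  d[i] + (d[i + 1] - d[i]) * (v[i] - volume_cm3) / (v[i] - v[i + 1])
}

#' Absolute volume receiving at least a dose (V_D)
#'
#' @param dvh A `dvh`.
#' @param dose Dose level (same unit as the DVH).
#' @return Volume in cm^3 (0 beyond the maximum dose), linearly
#'   interpolated.
#' @export
volume_at_dose <- function(dvh, dose) {
  stopifnot(dose >= 0)
  if (dose > max(dvh$dose)) return(0)
  approx(dvh$dose, dvh$volume_cm3, xout = dose, rule = 2)$y
}

#' Clinical organ-at-risk constraint presets
#'
#' The local clinical constraint table for the two prescriptions:
#' serial-organ limits to the hottest 0.1 cm^3 for brainstem, spinal
#' cord, optic nerves and optic chiasm, plus max/mean rules for the
#' remaining organs. `type` is one of `"dvol"` (D_volume, breach at or
#' above the limit), `"max"` (maximum dose must stay below the limit) or
#' `"mean"` (mean dose must not exceed the limit).
#'
#' @param patient_class `"adult"` or `"pediatric"`.
#' @param structures Optional character vector: keep only rules whose
#'   structure is listed (e.g. the structures a phantom actually has).
#' @return A tibble of class `constraint_set` with columns `structure`,
#'   `type`, `volume_cm3`, `limit`; attributes carry the prescription.
#' @export
constraint_set <- function(patient_class = c("adult", "pediatric"),
                           structures = NULL) {
  patient_class <- match.arg(patient_class)
  adult <- patient_class == "adult"
  tab <- tibble(
    structure = c("brainstem", "spinal_cord", "optic_nerve_L", "optic_nerve_R",
                  "optic_chiasm", "retina", "lenses", "inner_ear", "parotid"),
    type = c("dvol", "dvol", "dvol", "dvol", "dvol", "max", "max", "mean",
             "mean"),
    volume_cm3 = c(0.1, 0.1, 0.1, 0.1, 0.1, NA, NA, NA, NA),
    limit = if (adult) c(58, 58, 58, 58, 58, 49, 6.5, 52, 30)
            else c(50.4, 50, 50, 50, 50, 45, 6, 44, NA)
  )
  tab <- filter(tab, !is.na(.data$limit))
  if (!is.null(structures)) tab <- filter(tab, .data$structure %in% structures)
  structure(tab, class = c("constraint_set", class(tab)),
            prescription = prescription(patient_class))
}

#' Evaluate dose constraints on a plan dose grid
#'
#' Evaluates every rule of a constraint set with its proper statistic
#' (D_volume via the DVH, maximum, or mean) and reports value, limit,
#' margin and breach status. Following the "irradiated at or above the
#' constraint" convention, a `dvol` value exactly at the limit counts as
#' a breach; `max` rules breach at or above the limit, `mean` rules
#' breach strictly above it. For `dvol` rules the absolute volume
#' receiving at least the limit (`v_ge_limit_cm3`) is also reported.
#' Rules whose structure is missing from the phantom are skipped with an
#' explicit warning.
#'
#' @param grid A `dose_grid` (typically `"Gy(RBE)"`).
#' @param ph A `phantom`.
#' @param constraints A [constraint_set()] or compatible tibble.
#' @param bin_gy DVH bin width.
#' @return A `metric_report` tibble with one row per evaluated rule.
#' @export
evaluate_constraints <- function(grid, ph, constraints, bin_gy = 0.05) {
  rows <- vector("list", nrow(constraints))
  for (r in seq_len(nrow(constraints))) {
    cs <- constraints[r, ]
    msk <- ph$structures[[cs$structure]]
    if (is.null(msk) || !any(msk)) {
      warn(sprintf("structure '%s' missing from phantom: rule skipped",
                   cs$structure))
      next
    }
    vals <- grid$values[msk]
    v_ge <- NA_real_
    if (cs$type == "dvol") {
      dvh <- compute_dvh(grid, msk, ph, bin_gy = bin_gy)
      value <- dose_at_volume(dvh, volume_cm3 = min(cs$volume_cm3,
                                                    attr(dvh, "total_cm3")))
      v_ge <- volume_at_dose(dvh, cs$limit)
      breach <- value >= cs$limit
    } else if (cs$type == "max") {
      value <- max(vals)
      breach <- value >= cs$limit
    } else {
      value <- mean(vals)
      breach <- value > cs$limit
    }
    rows[[r]] <- tibble(
      structure = cs$structure, type = cs$type, volume_cm3 = cs$volume_cm3,
      value = value, limit = cs$limit, margin = cs$limit - value,
      breach = breach, v_ge_limit_cm3 = v_ge
    )
  }
  out <- bind_rows(rows)
  structure(out, class = c("metric_report", class(out)), unit = grid$unit)
}

#' CTV coverage metrics
#'
#' D95 (minimum dose to the hottest 95 percent of the CTV) in absolute
#' dose and as a percentage of the prescription, plus mean/median CTV
#' dose.
#'
#' @param grid A `dose_grid`.
#' @param ph A `phantom`.
#' @param presc Prescription row; default from the phantom class.
#' @param bin_gy DVH bin width.
#' @return One-row tibble with `d95`, `d95_pct`, `mean`, `median`.
#' @export
ctv_coverage <- function(grid, ph, presc = NULL, bin_gy = 0.05) {
  if (is.null(presc)) presc <- prescription(ph$patient_class)
  dvh <- compute_dvh(grid, "CTV", ph, bin_gy = bin_gy)
  d95 <- dose_at_volume(dvh, volume_pct = 95)
  vals <- grid$values[ph$structures$CTV]
  tibble(
    d95 = d95, d95_pct = 100 * d95 / presc$total_gy_rbe,
    mean = mean(vals), median = median(vals)
  )
}

#' Mean dose to the brain excluding the CTV
#'
#' The brain-minus-CTV mask is formed by set difference at evaluation
#' time.
#'
#' @param grid A `dose_grid`.
#' @param ph A `phantom`.
#' @return Mean dose (grid unit).
#' @export
mean_brain_minus_ctv <- function(grid, ph) {
  msk <- ph$structures$brain & !ph$structures$CTV
  mean(grid$values[msk])
}

#' Plot a cumulative DVH
#' @param object A `dvh`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dvh
#' @export
autoplot.dvh <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$dose, y = 100 * .data$volume_frac)) +
    geom_line() +
    labs(x = sprintf("Dose [%s]", attr(object, "unit")),
         y = "Volume [%]", title = attr(object, "structure_name"))
}
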