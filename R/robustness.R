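# Worst-case physical robustness analysis: 12 systematic error scenarios.

#' Enumerate the 12 physical uncertainty scenarios
#'
#' The cross product of the six single-axis isocenter shifts of 3 mm
#' (+/- x, y, z) with the two water-equivalent range scalings of
#' +/- 3.5 percent, giving exactly 12 scenarios. Every scenario pairs one
#' shift with one range error; the nominal (error-free) case is not a
#' scenario. Each scenario represents the same systematic error realized
#' throughout the whole treatment course.
#'
#' @param shift_mm Shift magnitude (default 3).
#' @param range_pct Range scaling magnitude in percent (default 3.5).
#' @return A 12-row tibble with `id`, `dx`, `dy`, `dz` (mm) and
#'   `range_scale`.
#' @export
scenario_table <- function(shift_mm = 3, range_pct = 3.5) {
  shifts <- tibble(
    axis = rep(c("x", "y", "z"), each = 2),
    sign = rep(c(+1, -1), times = 3)
  )
  grid <- tidyr::expand_grid(shifts, rs = c(+1, -1))
  mutate(grid,
         dx = ifelse(.data$axis == "x", .data$sign * shift_mm, 0),
         dy = ifelse(.data$axis == "y", .data$sign * shift_mm, 0),
         dz = ifelse(.data$axis == "z", .data$sign * shift_mm, 0),
         range_scale = 1 + .data$rs * range_pct / 100,
         id = sprintf("%s%+g_range%+.1fpct", .data$axis,
                      .data$sign * shift_mm, .data$rs * range_pct)) |>
    select("id", "dx", "dy", "dz", "range_scale")
}

#' Worst-case robustness analysis of a proton plan
#'
#' Recomputes the plan dose under each of the 12 systematic error
#' scenarios (constant RBE of 1.1 applied for metric evaluation),
#' evaluates every constraint plus CTV coverage per scenario, and
#' extracts per-metric worst-case values: the highest value over
#' scenarios for organ-at-risk metrics and the lowest for CTV coverage.
#' Also returns the per-structure DVH envelope (pointwise min/max over
#' scenarios) and the fraction of scenarios breaching each constraint.
#'
#' @param plan A `proton_plan`.
#' @param ph The `phantom`.
#' @param constraints A [constraint_set()]; defaults to the preset for
#'   the phantom class restricted to available structures.
#' @param scenarios Scenario tibble (default [scenario_table()]).
#' @param keep_grids Keep the 12 scenario dose grids in the result
#'   (default `FALSE` to save memory).
#' @param bin_gy DVH bin width.
#' @return An object of class `robustness_result`: list with `metrics`
#'   (long tibble over scenarios), `worst` (per-metric worst value and
#'   arg-scenario), `nominal` (nominal metric rows), `dvh_band`
#'   (pointwise envelope per structure), `breach` (per-constraint breach
#'   fraction over the 12 scenarios) and optionally `grids`.
#' @export
robustness_analysis <- function(plan, ph, constraints = NULL,
                                scenarios = scenario_table(),
                                keep_grids = FALSE, bin_gy = 0.05) {
  if (is.null(constraints)) {
    constraints <- constraint_set(ph$patient_class,
                                  structures = names(ph$structures))
  }
  presc <- plan$prescription
  eval_one <- function(grid, scen_id) {
    rep_ <- evaluate_constraints(grid, ph, constraints, bin_gy = bin_gy)
    cov <- ctv_coverage(grid, ph, presc, bin_gy = bin_gy)
    bind_rows(
      mutate(as_tibble(rep_), metric = paste0(.data$structure, "_",
                                              ifelse(.data$type == "dvol",
                                                     sprintf("D%.1fcc", .data$volume_cm3),
                                                     .data$type)),
             scenario = scen_id, kind = "oar"),
      tibble(structure = "CTV", type = "d95", volume_cm3 = NA,
             value = cov$d95_pct, limit = NA, margin = NA, breach = NA,
             v_ge_limit_cm3 = NA, metric = "CTV_D95pct", scenario = scen_id,
             kind = "ctv")
    )
  }
  nominal_rbe <- rbe_weighted_dose(plan$dose, model = "constant_1p1")
  nom <- eval_one(nominal_rbe, "nominal")

  structures <- unique(c(constraints$structure, "CTV"))
  band_env <- list()
  rows <- list()
  grids <- list()
  for (s in seq_len(nrow(scenarios))) {
    sc <- scenarios[s, ]
    g_phys <- apply_scenario(plan, ph, shift_mm = c(sc$dx, sc$dy, sc$dz),
                             range_scale = sc$range_scale,
                             scenario_id = sc$id)
    g <- rbe_weighted_dose(g_phys, model = "constant_1p1")
    rows[[s]] <- eval_one(g, sc$id)
    if (keep_grids) grids[[sc$id]] <- g
    for (nm in structures) {
      if (is.null(ph$structures[[nm]])) next
      dvh <- compute_dvh(g, nm, ph, bin_gy = bin_gy)
      cur <- approx(dvh$dose, dvh$volume_frac,
                    xout = seq(0, 85, by = bin_gy), rule = 2)$y
      if (is.null(band_env[[nm]])) {
        band_env[[nm]] <- list(lo = cur, hi = cur)
      } else {
        band_env[[nm]]$lo <- pmin(band_env[[nm]]$lo, cur)
        band_env[[nm]]$hi <- pmax(band_env[[nm]]$hi, cur)
      }
    }
  }
  metrics <- bind_rows(rows)
  worst <- metrics |>
    group_by(.data$metric, .data$kind) |>
    summarise(
      worst_value = ifelse(.data$kind[1] == "oar", max(.data$value),
                           min(.data$value)),
      worst_scenario = .data$scenario[
        if (.data$kind[1] == "oar") which.max(.data$value) else which.min(.data$value)],
      .groups = "drop"
    ) |>
    left_join(select(nom, "metric", nominal_value = "value", "limit"),
              by = "metric")
  breach <- metrics |>
    filter(.data$kind == "oar") |>
    group_by(.data$metric) |>
    summarise(n_breach = sum(.data$breach), n_scenarios = dplyr::n(),
              breach_fraction = .data$n_breach / .data$n_scenarios,
              .groups = "drop")
  dvh_band <- bind_rows(lapply(names(band_env), function(nm) {
    tibble(structure = nm, dose = seq(0, 85, by = bin_gy),
           volume_frac_min = band_env[[nm]]$lo,
           volume_frac_max = band_env[[nm]]$hi)
  }))
  structure(list(
    metrics = metrics, worst = worst, nominal = nom, breach = breach,
    dvh_band = dvh_band, scenarios = scenarios,
    grids = if (keep_grids) grids else NULL
  ), class = "robustness_result")
}

#' @export
print.robustness_result <- function(x, ...) {
  cat("<robustness_result> 12-scenario worst-case analysis\n")
  print(x$worst, n = Inf)
  invisible(x)
}

#' Tidy a robustness result
#' @param x A `robustness_result`.
#' @param ... Unused.
#' @return The long per-scenario metric tibble.
#' @method tidy robustness_result
#' @export
tidy.robustness_result <- function(x, ...) x$metrics

#' Plot the scenario DVH envelope of a structure
#' @param x A `robustness_result`.
#' @param structure Structure name.
#' @return A ggplot with the min/max scenario band.
#' @export
plot_dvh_band <- function(x, structure = "brainstem") {
  b <- filter(x$dvh_band, .data$structure == !!structure)
  ggplot(b, aes(x = .data$dose)) +
    geom_ribbon(aes(ymin = 100 * .data$volume_frac_min,
                    ymax = 100 * .data$volume_frac_max), alpha = 0.4) +
    labs(x = "Dose [Gy(RBE)]", y = "Volume [%]", title = structure)
}
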