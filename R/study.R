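# Desk-scale study orchestration: cohort generation, proton + photon
# planning, robustness and variable-RBE analyses, constraint reporting.

#' Study configuration
#'
#' @param n_adult,n_pediatric Cohort composition (default 6 adult + 4
#'   pediatric, the study cohort split).
#' @param seed Integer master seed; all randomness derives from it.
#' @param voxel_mm Phantom voxel size in mm (default 4, the desk-scale
#'   grid).
#' @param alpha_beta `(alpha/beta)_x` values (Gy) for variable-RBE
#'   analysis; default `c(2, 3, 4)` (2 Gy is typical for late-reacting
#'   brain tissue).
#' @param ctv_alpha_beta Tumor `(alpha/beta)_x` override (Gy) for the
#'   CTV-coverage sensitivity analysis (default 10).
#' @param beams Beam tibble (default [beam_star()]).
#' @param arc An [arc_spec()] for the photon surrogate.
#' @param bin_gy DVH bin width.
#' @param out_dir Optional output directory for tables, grids and
#'   provenance.
#' @param write_grids If `TRUE` and `out_dir` is set, serialize phantom
#'   and dose/LET grids as NIfTI.
#' @return A `study_config` list.
#' @export
study_config <- function(n_adult = 6, n_pediatric = 4, seed = 1L,
                         voxel_mm = 4, alpha_beta = c(2, 3, 4),
                         ctv_alpha_beta = 10, beams = beam_star(),
                         arc = arc_spec(), bin_gy = 0.05, out_dir = NULL,
                         write_grids = FALSE) {
  if (length(alpha_beta) < 1) {
    abort("alpha_beta must contain at least one value")
  }
  stopifnot(n_adult + n_pediatric >= 1, all(alpha_beta > 0), voxel_mm > 0)
  structure(list(
    n_adult = n_adult, n_pediatric = n_pediatric, seed = as.integer(seed),
    voxel_mm = voxel_mm, alpha_beta = alpha_beta,
    ctv_alpha_beta = ctv_alpha_beta, beams = beams, arc = arc,
    bin_gy = bin_gy, out_dir = out_dir, write_grids = write_grids
  ), class = "study_config")
}

#' Load a study configuration from a YAML file
#'
#' Scalar fields of [study_config()] can be set in a `study:` section;
#' unknown fields raise an error.
#'
#' @param path YAML file path.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  y <- y$study %||% y
  allowed <- c("n_adult", "n_pediatric", "seed", "voxel_mm", "alpha_beta",
               "ctv_alpha_beta", "bin_gy", "out_dir", "write_grids")
  bad <- setdiff(names(y), allowed)
  if (length(bad)) abort(paste("unknown config fields:", paste(bad, collapse = ", ")))
  do.call(study_config, y)
}

# Full single-phantom analysis: proton + photon plans, nominal metrics
# under each RBE model, and the 12-scenario worst case under RBE 1.1.
analyze_phantom <- function(ph, config, phantom_id = 1L) {
  presc <- prescription(ph$patient_class)
  plan <- plan_proton(ph, beams = config$beams, presc = presc)
  arc <- plan_arc(ph, presc = presc, arc = config$arc)
  cons <- constraint_set(ph$patient_class, structures = names(ph$structures))
  vv <- prod(ph$voxel_mm) / 1000
  ext <- ph$structures$external

  metric_rows <- function(grid, analysis) {
    rep_ <- evaluate_constraints(grid, ph, cons, bin_gy = config$bin_gy)
    cov <- ctv_coverage(grid, ph, presc, bin_gy = config$bin_gy)
    bind_rows(
      tibble(metric = paste0(rep_$structure, "_value"), value = rep_$value),
      tibble(metric = paste0(rep_$structure, "_v_ge_limit_cm3"),
             value = rep_$v_ge_limit_cm3),
      tibble(metric = "ctv_d95_pct", value = cov$d95_pct),
      tibble(metric = "ctv_mean", value = cov$mean),
      tibble(metric = "mean_brain_minus_ctv",
             value = mean_brain_minus_ctv(grid, ph)),
      tibble(metric = "integral_dose_gy_l",
             value = sum(grid$values[ext]) * vv / 1000)
    ) |>
      mutate(analysis = analysis, phantom = phantom_id,
             patient_class = ph$patient_class)
  }

  grids <- list(
    rbe1.1_nominal = rbe_weighted_dose(plan$dose, model = "constant_1p1"),
    photon = dose_grid(arc$dose$values, "Gy(RBE)", meta = arc$dose$meta)
  )
  for (ab in config$alpha_beta) {
    grids[[sprintf("mcnamara_ab%g", ab)]] <- rbe_weighted_dose(
      plan$dose, plan$letd, model = "mcnamara", alpha_beta_x = ab,
      n_fractions = presc$n_fractions)
  }
  grids[["mcnamara_ctv10"]] <- rbe_weighted_dose(
    plan$dose, plan$letd, model = "mcnamara",
    alpha_beta_x = c(.default = min(config$alpha_beta),
                     CTV = config$ctv_alpha_beta),
    n_fractions = presc$n_fractions, ph = ph)

  metrics <- bind_rows(Map(metric_rows, grids, names(grids)))

  rob <- robustness_analysis(plan, ph, constraints = cons,
                             bin_gy = config$bin_gy)
  worst_rows <- bind_rows(
    rob$metrics |>
      filter(.data$kind == "oar") |>
      group_by(.data$structure) |>
      summarise(value = max(.data$v_ge_limit_cm3), .groups = "drop") |>
      mutate(metric = paste0(.data$structure, "_v_ge_limit_cm3")) |>
      select("metric", "value"),
    rob$worst |>
      filter(.data$kind == "oar") |>
      transmute(metric = paste0(sub("_D.*|_max|_mean", "", .data$metric),
                                "_value"),
                value = .data$worst_value),
    tibble(metric = "ctv_d95_pct",
           value = rob$worst$worst_value[rob$worst$metric == "CTV_D95pct"])
  ) |>
    mutate(analysis = "rbe1.1_worst", phantom = phantom_id,
           patient_class = ph$patient_class)

  list(metrics = bind_rows(metrics, worst_rows),
       robustness = rob, plan = plan, arc = arc, grids = grids)
}

#' Run the full desk-scale study
#'
#' Generates the seeded synthetic cohort, forward-computes the proton and
#' photon-surrogate plans, evaluates nominal metrics under constant RBE
#' 1.1 and the McNamara model for each configured `(alpha/beta)_x`
#' (plus the high tumor `(alpha/beta)_x` CTV variant), runs the
#' 12-scenario worst-case robustness analysis, converts the shipped
#' EQD2-style constraint table to the adult fractionation, and aggregates
#' cohort summaries. Fully deterministic under the config seed.
#'
#' @param config A [study_config()].
#' @return An object of class `proton_study`: list with `metrics` (long
#'   tibble: phantom, patient_class, analysis, metric, value),
#'   `summary` (per class/analysis/metric mean and sd), `breach`
#'   (per-constraint scenario breach counts pooled over the cohort),
#'   `eqd2` (converted constraint table), `phantoms` (structure-volume
#'   tables) and `config`.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  n <- config$n_adult + config$n_pediatric
  base <- phantom_spec(voxel_mm = config$voxel_mm,
                       random_seed = config$seed)
  phantoms <- sample_cohort(n, base_spec = base, seed = config$seed,
                            adult_fraction = config$n_adult / n)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    res[[i]] <- analyze_phantom(phantoms[[i]], config, phantom_id = i)
  }
  metrics <- bind_rows(lapply(res, `[[`, "metrics"))
  summary <- metrics |>
    group_by(.data$patient_class, .data$analysis, .data$metric) |>
    summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
              n = dplyr::n(), .groups = "drop")
  breach <- bind_rows(lapply(seq_len(n), function(i) {
    mutate(res[[i]]$robustness$breach, phantom = i,
           patient_class = phantoms[[i]]$patient_class)
  })) |>
    group_by(.data$metric) |>
    summarise(n_breach = sum(.data$n_breach),
              n_scenarios = sum(.data$n_scenarios),
              breach_fraction = .data$n_breach / .data$n_scenarios,
              .groups = "drop")
  d1 <- prescription("adult")$dose_per_fraction_gy_rbe
  eqd2 <- eqd_convert_table(eqd2_constraints(), d1 = d1)

  study <- structure(list(
    metrics = metrics, summary = summary, breach = breach, eqd2 = eqd2,
    phantoms = lapply(phantoms, structure_volumes),
    robustness = lapply(res, `[[`, "robustness"),
    config = config
  ), class = "proton_study")

  if (!is.null(config$out_dir)) {
    write_study(study, res, phantoms, config)
  }
  study
}

# Serialize study artifacts: tidy CSV tables, provenance JSON, and
# (optionally) phantom + dose/LET grids as NIfTI.
write_study <- function(study, res, phantoms, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study$metrics, file.path(config$out_dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(study$summary, file.path(config$out_dir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(study$breach, file.path(config$out_dir, "breach.csv"),
                   row.names = FALSE)
  utils::write.csv(study$eqd2,
                   file.path(config$out_dir, "constraints_converted.csv"),
                   row.names = FALSE)
  utils::write.csv(scenario_table(), file.path(config$out_dir, "scenarios.csv"),
                   row.names = FALSE)
  dvh_band <- bind_rows(lapply(seq_along(res), function(i) {
    mutate(res[[i]]$robustness$dvh_band, phantom = i)
  }))
  utils::write.csv(dvh_band, file.path(config$out_dir, "dvh_bands.csv"),
                   row.names = FALSE)
  prov <- list(
    package = "protonplan",
    version = as.character(utils::packageVersion("protonplan")),
    seed = config$seed,
    config = config[c("n_adult", "n_pediatric", "voxel_mm", "alpha_beta",
                      "ctv_alpha_beta", "bin_gy")],
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  if (isTRUE(config$write_grids)) {
    for (i in seq_along(phantoms)) {
      pdir <- file.path(config$out_dir, sprintf("phantom_%02d", i))
      write_phantom(phantoms[[i]], pdir)
      write_grid(res[[i]]$plan$dose, file.path(pdir, "dose_proton.nii.gz"),
                 phantoms[[i]]$voxel_mm)
      write_grid(res[[i]]$plan$letd, file.path(pdir, "letd.nii.gz"),
                 phantoms[[i]]$voxel_mm)
      for (nm in names(res[[i]]$grids)) {
        write_grid(res[[i]]$grids[[nm]],
                   file.path(pdir, paste0("dose_", nm, ".nii.gz")),
                   phantoms[[i]]$voxel_mm)
      }
    }
  }
  invisible(config$out_dir)
}

#' Shipped EQD2-style constraint table
#'
#' A small, user-editable table of serial-organ constraints expressed as
#' equivalent total dose in 2 Gy(RBE) fractions with the
#' `(alpha/beta)_x` values assumed for each organ. The shipped values are
#' representative synthetic defaults for the intracranial organs at risk
#' considered here (consensus-style EQD2 limits); they are inputs to
#' [eqd_convert_table()], not measurements.
#'
#' @return A tibble with `structure`, `limit_eqd2`, `alpha_beta_x`.
#' @export
eqd2_constraints <- function() {
  path <- system.file("extdata", "eqd2_constraints_synthetic.csv",
                      package = "protonplan")
  as_tibble(utils::read.csv(path))
}

#' @export
print.proton_study <- function(x, ...) {
  cat(sprintf("<proton_study> %d phantoms (%d adult / %d pediatric), seed %d\n",
              x$config$n_adult + x$config$n_pediatric, x$config$n_adult,
              x$config$n_pediatric, x$config$seed))
  print(glance(x))
  invisible(x)
}

#' Tidy the study metrics
#' @param x A `proton_study`.
#' @param ... Unused.
#' @return The long metric tibble.
#' @method tidy proton_study
#' @export
tidy.proton_study <- function(x, ...) x$metrics

#' One-row study summary
#' @param x A `proton_study`.
#' @param ... Unused.
#' @return A one-row tibble with headline cohort means.
#' @method glance proton_study
#' @export
glance.proton_study <- function(x, ...) {
  g <- function(analysis, metric) {
    mean(filter(x$metrics, .data$analysis == !!analysis,
                .data$metric == !!metric)$value)
  }
  bs <- x$breach[x$breach$metric == "brainstem_D0.1cc", ]
  tibble(
    n_phantoms = x$config$n_adult + x$config$n_pediatric,
    ctv_d95_pct_nominal = g("rbe1.1_nominal", "ctv_d95_pct"),
    ctv_d95_pct_worst = g("rbe1.1_worst", "ctv_d95_pct"),
    brain_minus_ctv_proton = g("rbe1.1_nominal", "mean_brain_minus_ctv"),
    brain_minus_ctv_photon = g("photon", "mean_brain_minus_ctv"),
    brainstem_v_nominal = g("rbe1.1_nominal", "brainstem_v_ge_limit_cm3"),
    brainstem_v_worst = g("rbe1.1_worst", "brainstem_v_ge_limit_cm3"),
    brainstem_breach_fraction = if (nrow(bs)) bs$breach_fraction else NA_real_
  )
}

#' Constraint-volume summary plot
#'
#' Volume of a structure irradiated at or above its constraint across the
#' cohort, by analysis (nominal, worst-case, variable RBE) — the
#' headline organ-at-risk uncertainty figure.
#'
#' @param x A `proton_study`.
#' @param structure Structure name (default `"brainstem"`).
#' @return A ggplot.
#' @export
plot_constraint_volume <- function(x, structure = "brainstem") {
  m <- filter(x$metrics,
              .data$metric == paste0(structure, "_v_ge_limit_cm3"))
  ggplot(m, aes(x = .data$analysis, y = .data$value)) +
    ggplot2::geom_boxplot() +
    labs(x = NULL, y = sprintf("%s volume at/above constraint [cm^3]", structure))
}
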