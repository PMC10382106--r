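#' Configuration for an end-to-end analysis run
#'
#' @param seed master integer seed; every random stage derives its seed
#'   from it.
#' @param regions regions to model (default the 13 modelled regions).
#' @param thresholds extreme-deviation thresholds, ascending positive
#'   (defaults 1.65, 2.3, 2.6, corresponding to normal-tail levels 0.05,
#'   0.01 and 0.005).
#' @param fdr_alpha nominal false-discovery level used when reporting.
#' @param n_normative,n_chd simulated cohort sizes when no input paths are
#'   given (defaults 219 and 36).
#' @param curve_params,effect_specs simulator configuration.
#' @param model a [gp_control()] for the normative fits.
#' @param normative_path,chd_scans_path,covariates_path optional CSV paths;
#'   when given they replace the corresponding simulated table.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1, regions = modelled_regions(),
                       thresholds = c(1.65, 2.3, 2.6), fdr_alpha = 0.05,
                       n_normative = 219, n_chd = 36,
                       curve_params = default_curve_params(),
                       effect_specs = default_effect_specs(),
                       model = gp_control(seed = seed),
                       normative_path = NULL, chd_scans_path = NULL,
                       covariates_path = NULL) {
  if (is.unsorted(thresholds) || any(thresholds <= 0)) {
    stop("thresholds must be positive and ascending", call. = FALSE)
  }
  if (fdr_alpha <= 0 || fdr_alpha >= 1) {
    stop("fdr_alpha must lie in (0, 1)", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), regions = regions,
                 thresholds = thresholds, fdr_alpha = fdr_alpha,
                 n_normative = n_normative, n_chd = n_chd,
                 curve_params = curve_params, effect_specs = effect_specs,
                 model = model, normative_path = normative_path,
                 chd_scans_path = chd_scans_path,
                 covariates_path = covariates_path),
            class = "run_config")
}

# the statistical families mirroring the published analysis plan
family_plan <- function() {
  list(
    list(test = "wilcoxon"),
    list(test = "kruskal_wallis", var = "chd_category"),
    list(test = "spearman", var = "age_surgery_days"),
    list(test = "spearman", var = "interscan_days"),
    list(test = "spearman", var = "surgery_to_postmri_days"),
    list(test = "partial_spearman", var = "picu_days",
         given = "age_surgery_days"),
    list(test = "partial_spearman", var = "bypass_min",
         given = "picu_days"),
    list(test = "partial_spearman", var = "arrest_min",
         given = "picu_days"),
    list(test = "partial_spearman", var = "creatinine_umol_l",
         given = "age_creatinine_days"),
    list(test = "mann_whitney", var = "rrt"),
    list(test = "mann_whitney", var = "nec"),
    list(test = "spearman", var = "ventilation_days"),
    list(test = "spearman", var = "inotrope_days"),
    list(test = "spearman", var = "d_weight_z"),
    list(test = "spearman", var = "d_hc_z")
  )
}

#' Run the full perioperative growth analysis
#'
#' Strings the pipeline end to end: obtain (or simulate) the normative and
#' surgical cohorts, fit per-region Gaussian-process normative curves,
#' score the pre- and post-operative scans as deviation Z-scores, build
#' per-infant Z-slope trajectories, take the extreme-deviation census, and
#' run every clinical-association family (pre-vs-post Wilcoxon;
#' Kruskal-Wallis across CHD categories; Spearman against age at surgery,
#' scan timing, ventilation, inotropes and somatic growth; partial Spearman
#' for PICU days given age at surgery, bypass and circulatory arrest given
#' PICU days, and creatinine given age at measurement; Mann-Whitney for
#' renal replacement and necrotising enterocolitis) with
#' Benjamini-Hochberg adjustment within each family.
#'
#' @param config a [run_config()].
#' @return list of class `growth_report`: `inputs`, `models`,
#'   `model_summary`, `scores`, `trajectories`, `census`, `families`
#'   (named list of per-region TestResult tables) and `provenance`.
#' @export
run_full_analysis <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  normative <- if (is.null(config$normative_path)) {
    simulate_normative(config$curve_params, n = config$n_normative,
                       seed = config$seed)
  } else read_scan_table(config$normative_path)

  if (is.null(config$chd_scans_path)) {
    chd <- simulate_chd(config$curve_params, config$effect_specs,
                        n = config$n_chd, seed = config$seed + 1L)
    chd_scans <- chd$scans
    covariates <- chd$covariates
  } else {
    chd_scans <- read_scan_table(config$chd_scans_path)
    covariates <- read_covariate_table(config$covariates_path)
  }
  covariates$d_weight_z <- covariates$weight_z_post - covariates$weight_z_pre
  covariates$d_hc_z <- covariates$hc_z_post - covariates$hc_z_pre

  ctl <- config$model
  ctl$seed <- config$seed
  models <- fit_all_regions(normative, regions = config$regions,
                            control = ctl)

  scores_pre <- score_scans(models, chd_scans[chd_scans$timepoint == "pre", ])
  scores_post <- score_scans(models,
                             chd_scans[chd_scans$timepoint == "post", ])
  trajectories <- build_trajectories(scores_pre, scores_post,
                                     thresholds = config$thresholds)
  cats <- stats::setNames(covariates$chd_category, covariates$subject_id)
  cen <- census(trajectories, thresholds = config$thresholds,
                categories = cats)

  families <- list()
  for (f in family_plan()) {
    key <- paste(c(f$test, f$var), collapse = ".")
    families[[key]] <- run_region_family(
      trajectories, covariates, test = f$test, var = f$var,
      given = f$given)
  }

  # exposure-level somatic cross-checks (one family, not per region)
  som <- do.call(rbind, lapply(
    c("age_surgery_days", "bypass_min", "arrest_min", "picu_days"),
    function(v) {
      rbind(cbind(variable = paste0("d_weight_z~", v),
                  spearman(covariates$d_weight_z, covariates[[v]],
                           family = "somatic_exposures")),
            cbind(variable = paste0("d_hc_z~", v),
                  spearman(covariates$d_hc_z, covariates[[v]],
                           family = "somatic_exposures")))
    }))
  som$p_fdr <- bh_fdr(som$p_raw)
  families[["somatic_exposures"]] <- som

  model_summary <- do.call(rbind, lapply(unclass(models), function(m) {
    data.frame(region = m$region, n = m$n, lml = m$lml,
               t(as.matrix(m$hyperparams)), stringsAsFactors = FALSE)
  }))
  rownames(model_summary) <- NULL

  provenance <- list(
    package_version = as.character(utils::packageVersion("neonorm")),
    seed = config$seed,
    config_hash = data_hash(config),
    normative_hash = data_hash(normative),
    chd_hash = data_hash(chd_scans),
    covariate_hash = data_hash(covariates),
    thresholds = config$thresholds,
    fdr_alpha = config$fdr_alpha)

  structure(list(inputs = list(normative = normative,
                               chd_scans = chd_scans,
                               covariates = covariates),
                 models = models, model_summary = model_summary,
                 scores = rbind(scores_pre, scores_post),
                 trajectories = trajectories, census = cen,
                 families = families, provenance = provenance),
            class = "growth_report")
}

#' @export
print.growth_report <- function(x, ...) {
  cat("Perioperative brain-growth analysis\n")
  cat(sprintf("  normative cohort: %d scans; surgical cohort: %d scans (%d infants)\n",
              nrow(x$inputs$normative), nrow(x$inputs$chd_scans),
              nrow(x$inputs$covariates)))
  cat(sprintf("  %d normative region models; seed %d; config %s\n",
              length(x$models), x$provenance$seed,
              x$provenance$config_hash))
  print(x$census)
  alpha <- x$provenance$fdr_alpha
  cat(sprintf("  association families (regions with P_FDR < %.2f):\n", alpha))
  for (nm in names(x$families)) {
    f <- x$families[[nm]]
    sig <- f$region[!is.na(f$p_fdr) & f$p_fdr < alpha]
    cat(sprintf("    %-42s %s\n", nm,
                if (length(sig)) paste(sig, collapse = ", ") else "-"))
  }
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits the per-scan Z-score table, trajectory table and family tables as
#' CSV, the census and provenance as JSON, the fitted models as JSON, and
#' normative centile curves as CSV.
#'
#' @param report a `growth_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table_csv(report$scores, file.path(dir, "z_scores.csv"))
  write_table_csv(report$trajectories, file.path(dir, "trajectories.csv"))
  write_table_csv(report$model_summary, file.path(dir, "model_summary.csv"))
  for (nm in names(report$families)) {
    write_table_csv(report$families[[nm]],
                    file.path(dir, sprintf("family_%s.csv", nm)))
  }
  cent <- do.call(rbind, lapply(unclass(report$models), centile_table))
  write_table_csv(cent, file.path(dir, "centiles.csv"))
  jsonlite::write_json(unclass(report$census),
                       file.path(dir, "census.json"),
                       digits = NA, auto_unbox = TRUE)
  jsonlite::write_json(report$provenance, file.path(dir, "provenance.json"),
                       digits = NA, auto_unbox = TRUE)
  write_models_json(report$models, file.path(dir, "models.json"))
  invisible(dir)
}
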