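# End-to-end orchestration: preprocessing once, then a global CCA on all
# imaging + behavioral features and 'modular' CCAs per imaging modality,
# each with Wilks tests, permutation inference and k-fold cross-validation.

#' Feature metadata mirroring the study schema
#'
#' The analysis schema used throughout the examples and the synthetic study
#' scenario: 56 imaging features (34 structural cortical-thickness, 12
#' task-activation, 10 resting-state connectivity) and 23 behavioral features
#' (6 clinical, 2 daily-functioning, 15 cognitive). Clinical and functioning
#' scales are patient-referenced and reverse-coded (higher raw scores mean
#' more symptoms/impairment); completion-time and error-count cognitive
#' scores are reverse-coded.
#'
#' @return list with data frames \code{meta_x} and \code{meta_y} in the
#'   format of [feature_table()].
#' @export
study_schema <- function() {
  meta_x <- data.frame(
    name = c(sprintf("ct_%02d", 1:34), sprintf("task_%02d", 1:12), sprintf("rest_%02d", 1:10)),
    modality = rep(c("structural", "task", "resting"), c(34, 12, 10)),
    reverse = FALSE, reference = "control", stringsAsFactors = FALSE)
  cog <- c("ravlt_t15", "ravlt_t6", "ravlt_delayed", "ravlt_recognition",
           "tmt_a", "tmt_b", "rbans_coding", "rbans_digitspan", "wais_lns",
           "fluency_s", "fluency_d", "rvp_a", "rvp_latency", "swm_errors",
           "swm_strategy")
  meta_y <- data.frame(
    name = c("illness_duration", "n_depressive", "n_manic", "n_mixed",
             "hdrs", "ymrs", "fast_total", "wsas_total", cog),
    modality = rep(c("clinical", "functioning", "cognitive"), c(6, 2, 15)),
    reverse = c(rep(TRUE, 8),
                cog %in% c("tmt_a", "tmt_b", "rvp_latency", "swm_errors")),
    reference = rep(c("patient", "control"), c(8, 15)),
    stringsAsFactors = FALSE)
  list(meta_x = meta_x, meta_y = meta_y)
}

#' Generate a synthetic cohort on the study schema
#'
#' Convenience wrapper around [cca_spec()]/[generate_cohort()] producing the
#' full study-sized scenario: 167 patients and 46 matched controls, 56
#' imaging and 23 behavioral features tagged per [study_schema()], one
#' planted canonical pair, linear age/sex effects, sparse MCAR missingness
#' in the behavioral table and rare heavy outliers.
#'
#' @param seed integer seed.
#' @param rho planted canonical correlations (default 0.84).
#' @param noise_sd feature noise SD (default 1, comparable to the unit-scale
#'   latent signal per feature).
#' @param missing_rate behavioral MCAR rate (default 0.008).
#' @param outlier_rate heavy-outlier cell rate (default 0.005).
#' @return a [generate_cohort()] result with schema metadata attached.
#' @export
generate_study_cohort <- function(seed = 1, rho = 0.84, noise_sd = 1,
                                  missing_rate = 0.008, outlier_rate = 0.005) {
  sch <- study_schema()
  spec <- cca_spec(n_patients = 167, n_controls = 46, p = 56, q = 23,
                   rho = rho, noise_sd = noise_sd,
                   age_beta = with_seed(seed + 31L, stats::rnorm(79, sd = 0.02)),
                   sex_beta = with_seed(seed + 32L, stats::rnorm(79, sd = 0.3)),
                   missing_rate = missing_rate, outlier_rate = outlier_rate,
                   seed = seed)
  generate_cohort(spec, meta_x = sch$meta_x, meta_y = sch$meta_y)
}

run_model <- function(x, y, name, n_perm, k_folds, seed, threshold) {
  fit <- cca_fit(x, y)
  perm <- permutation_test(x, y, n_perm = n_perm, seed = seed + 1L)
  cv <- cross_validate(x, y, k = k_folds, seed = seed + 2L)
  cross <- fit$cross_y[, 1]
  sub <- flag_substantial(fit$cross_y, threshold)[, 1]
  sub_tab <- data.frame(feature = names(cross)[sub], cross_loading = unname(cross[sub]))
  sub_tab <- sub_tab[order(-abs(sub_tab$cross_loading)), , drop = FALSE]
  rownames(sub_tab) <- NULL
  list(model = name, n = fit$n, p = fit$p, q = fit$q,
       r = fit$r, wilks = fit$wilks,
       perm_p = perm$p_value, n_perm = perm$n_perm,
       cv_mean = cv$mean_r, cv_sd = cv$sd_r, fold_r = cv$fold_r,
       loadings_x = fit$loadings_x, loadings_y = fit$loadings_y,
       cross_x = fit$cross_x, cross_y = fit$cross_y,
       substantial_cross_y = sub_tab, threshold = threshold,
       fit = fit)
}

#' Global CCA on preprocessed tables
#'
#' Runs the full inferential chain — CCA, Wilks tests, permutation test of
#' the first canonical correlation, k-fold cross-validation, loading and
#' cross-loading flags — on the patients' preprocessed imaging and
#' behavioral matrices (all modalities).
#'
#' @param prep a [preprocess()] result.
#' @param n_perm permutations (default 10000).
#' @param k_folds CV folds (default 10).
#' @param seed integer seed for permutation and fold randomness.
#' @param threshold substantiality cut-off for loadings (default 0.3).
#' @return a model-report list (canonical correlations, Wilks table,
#'   permutation p, CV mean/SD, loadings, substantial cross-loadings).
#' @export
run_global <- function(prep, n_perm = 10000, k_folds = 10, seed = 1, threshold = 0.3) {
  stopifnot(inherits(prep, "preprocess_result"))
  pat <- prep$x$group == "patient"
  run_model(prep$x$values[pat, , drop = FALSE], prep$y$values[pat, , drop = FALSE],
            "global", n_perm, k_folds, seed, threshold)
}

#' Modular CCA restricted to one imaging modality
#'
#' Same chain as [run_global()], with the imaging set restricted to the
#' features of one modality tag; the globally preprocessed matrices are
#' reused (subset by column), not re-preprocessed.
#'
#' @inheritParams run_global
#' @param modality one of the modality tags in the imaging metadata
#'   (e.g. "structural", "task", "resting").
#' @return a model-report list.
#' @export
run_modular <- function(prep, modality, n_perm = 10000, k_folds = 10, seed = 1,
                        threshold = 0.3) {
  stopifnot(inherits(prep, "preprocess_result"))
  tags <- unique(prep$x$meta$modality)
  if (!modality %in% tags) stopf("unknown modality '%s'; available: %s",
                                 modality, paste(tags, collapse = ", "))
  cols <- prep$x$meta$name[prep$x$meta$modality == modality]
  if (length(cols) < 2) stopf("modality '%s' has fewer than 2 features", modality)
  pat <- prep$x$group == "patient"
  run_model(prep$x$values[pat, cols, drop = FALSE],
            prep$y$values[pat, , drop = FALSE],
            modality, n_perm, k_folds, seed, threshold)
}

#' Run the full analysis from a configuration
#'
#' One preprocessing pass over the raw tables, then the global CCA and a
#' modular CCA per requested imaging modality, collected in an analysis
#' report. All randomness derives from \code{seed}; the same configuration
#' and seed reproduce every output byte. The four model p-values are
#' reported uncorrected (as many multimodal CCA applications do); set
#' \code{bonferroni = TRUE} to add Bonferroni-adjusted permutation p-values
#' across the models run.
#'
#' @param x_table,y_table raw [feature_table()]s, or a
#'   \code{synthetic_cohort} passed as \code{x_table}.
#' @param covariates data frame (subject_id, age, sex); taken from the
#'   cohort when one is supplied.
#' @param config list of settings: \code{n_perm} (default 10000),
#'   \code{k_folds} (10), \code{seed} (required), \code{winsor_limit} (3),
#'   \code{threshold} (0.3), \code{modalities} (all imaging tags),
#'   \code{pairing} (optional hemisphere pairing), \code{bonferroni}
#'   (FALSE), \code{out_dir} (optional; written via [write_report()]).
#' @return object of class \code{"analysis_report"}: per-model results,
#'   preprocessing report, config echo and package version.
#' @export
run_analysis <- function(x_table, y_table = NULL, covariates = NULL, config = list()) {
  if (inherits(x_table, "synthetic_cohort")) {
    cohort <- x_table
    x_table <- cohort$x_table
    y_table <- cohort$y_table
    covariates <- covariates %||% cohort$covariates
  }
  if (is.null(config$seed)) stopf("config$seed is required")
  seed <- as.integer(config$seed)
  n_perm <- config$n_perm %||% 10000
  k_folds <- config$k_folds %||% 10
  winsor_limit <- config$winsor_limit %||% 3
  threshold <- config$threshold %||% 0.3
  if (threshold <= 0 || threshold >= 1) stopf("substantiality threshold must be in (0, 1)")

  prep <- preprocess(x_table, y_table, covariates, winsor_limit = winsor_limit,
                     pairing = config$pairing)
  modalities <- config$modalities %||% unique(prep$x$meta$modality)
  models <- list(global = run_global(prep, n_perm, k_folds, seed, threshold))
  for (i in seq_along(modalities)) {
    mod <- modalities[i]
    models[[mod]] <- run_modular(prep, mod, n_perm, k_folds, seed + 100L * i, threshold)
  }
  if (isTRUE(config$bonferroni)) {
    for (nm in names(models)) models[[nm]]$perm_p_bonferroni <- min(1, models[[nm]]$perm_p * length(models))
  }
  report <- structure(list(
    models = models,
    preprocess_report = prep$report,
    config = list(n_perm = n_perm, k_folds = k_folds, seed = seed,
                  winsor_limit = winsor_limit, threshold = threshold,
                  modalities = modalities, bonferroni = isTRUE(config$bonferroni)),
    version = as.character(utils::packageVersion("braincca"))
  ), class = "analysis_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Brain-behavior CCA analysis report\n")
  for (m in x$models) {
    cat(sprintf("  %-12s r1 = %.2f, permutation p = %.4g, CV mean r = %.2f (SD %.2f), p = %d, q = %d\n",
                m$model, m$r[1], m$perm_p, m$cv_mean, m$cv_sd, m$p, m$q))
  }
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Emits a machine-readable JSON report, TSV loading/cross-loading matrices
#' per model, and a plain-text summary that mirrors the conventional
#' reporting style (r, permutation p, CV mean ± SD, substantial
#' cross-loadings in descending magnitude).
#'
#' @param report an [run_analysis()] result.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the path of the JSON report.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  json <- list(config = report$config, version = report$version, models = list())
  txt <- c("Brain-behavior CCA analysis", "===========================", "")
  for (m in report$models) {
    json$models[[m$model]] <- list(
      n = m$n, p = m$p, q = m$q, r = m$r,
      wilks = m$wilks, perm_p = m$perm_p, n_perm = m$n_perm,
      cv_mean = m$cv_mean, cv_sd = m$cv_sd, fold_r = m$fold_r,
      substantial_cross_y = m$substantial_cross_y)
    for (part in c("loadings_x", "loadings_y", "cross_x", "cross_y")) {
      tab <- data.frame(feature = rownames(m[[part]]), m[[part]], check.names = FALSE)
      utils::write.table(tab, file.path(out_dir, sprintf("%s_%s.tsv", m$model, part)),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    txt <- c(txt, sprintf("%s model (p = %d imaging, q = %d behavioral, n = %d patients)",
                          m$model, m$p, m$q, m$n),
             sprintf("  first canonical correlation r = %.2f, permutation p = %.4g (%d permutations)",
                     m$r[1], m$perm_p, m$n_perm),
             sprintf("  cross-validation: mean r = %.2f, SD = %.2f (%d folds)",
                     m$cv_mean, m$cv_sd, length(m$fold_r)),
             sprintf("  Wilks' lambda first pair: lambda = %.3f, p = %.4g",
                     m$wilks$lambda[1], m$wilks$p_value[1]))
    if (nrow(m$substantial_cross_y)) {
      txt <- c(txt, "  substantial behavioral cross-loadings (|value| > threshold):",
               sprintf("    %-20s %6.2f", m$substantial_cross_y$feature,
                       m$substantial_cross_y$cross_loading), "")
    } else {
      txt <- c(txt, sprintf("  no cross-loadings exceed threshold %.2f", m$threshold), "")
    }
  }
  path <- file.path(out_dir, "report.json")
  jsonlite::write_json(json, path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  writeLines(txt, file.path(out_dir, "summary.txt"))
  invisible(path)
}
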