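# Reference-cohort preprocessing chain:
# average_hemispheres -> standardize_to_reference -> winsorize ->
# reverse_code -> impute_regression -> residualize_covariates,
# plus normality diagnostics (Shapiro-Wilk, Mardia).

#' Average paired left/right hemisphere features
#'
#' Cortical measures estimated separately per hemisphere are collapsed to
#' their arithmetic mean per region, halving the structural feature count
#' (e.g. 68 regional thickness values become 34) to keep the
#' subject-to-variable ratio workable for CCA.
#'
#' @param table a [feature_table()].
#' @param pairing data frame with columns \code{region}, \code{left},
#'   \code{right} naming each bilateral pair; the averaged feature takes the
#'   region name and the left feature's metadata.
#' @return a \code{feature_table} with each pair replaced by its mean;
#'   unpaired features pass through unchanged.
#' @export
average_hemispheres <- function(table, pairing) {
  stopifnot(inherits(table, "feature_table"))
  check_stage(table, "average_hemispheres")
  if (!all(c("region", "left", "right") %in% names(pairing))) {
    stopf("pairing needs columns region, left, right")
  }
  feats <- colnames(table$values)
  bad <- setdiff(c(pairing$left, pairing$right), feats)
  if (length(bad)) stopf("pairing names feature(s) not in table: %s", paste(bad, collapse = ", "))
  if (anyDuplicated(c(pairing$left, pairing$right))) stopf("a feature appears in more than one pair")

  avg <- (table$values[, pairing$left, drop = FALSE] +
          table$values[, pairing$right, drop = FALSE]) / 2
  colnames(avg) <- pairing$region
  keep <- setdiff(feats, c(pairing$left, pairing$right))
  values <- cbind(avg, table$values[, keep, drop = FALSE])

  meta_pair <- table$meta[match(pairing$left, table$meta$name), ]
  meta_pair$name <- pairing$region
  meta <- rbind(meta_pair, table$meta[match(keep, table$meta$name), ])
  out <- feature_table(values, table$group, meta)
  mark_stage(out, "average_hemispheres")
}

#' Standardize features against their declared reference group
#'
#' Computes z-scores \eqn{(x - \bar{x}_{ref}) / s_{ref}} per feature, where
#' the reference sample is the group declared in the feature metadata:
#' healthy controls by default, so patient scores express deviation from
#' normative values; the patient sample for clinical/functioning scales.
#' Reference statistics use the non-missing values of the reference group
#' only; the transform is applied to every subject. Missing cells stay
#' missing.
#'
#' @param table a [feature_table()], raw scale.
#' @return list with the standardized \code{table} and \code{reference_stats}
#'   (data frame: feature, reference group, mean, sd, n used).
#' @export
standardize_to_reference <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  check_stage(table, "standardize")
  vals <- table$values
  stats_out <- data.frame(name = table$meta$name, reference = table$meta$reference,
                          mean = NA_real_, sd = NA_real_, n_ref = NA_integer_,
                          stringsAsFactors = FALSE)
  for (j in seq_len(ncol(vals))) {
    ref_rows <- table$group == table$meta$reference[j]
    v <- vals[ref_rows, j]
    v <- v[!is.na(v)]
    if (length(v) < 2) stopf("feature '%s': reference group '%s' has < 2 non-missing values",
                             table$meta$name[j], table$meta$reference[j])
    m <- mean(v)
    s <- stats::sd(v)
    if (s == 0) stopf("feature '%s': zero SD in reference group '%s'",
                      table$meta$name[j], table$meta$reference[j])
    vals[, j] <- (vals[, j] - m) / s
    stats_out$mean[j] <- m
    stats_out$sd[j] <- s
    stats_out$n_ref[j] <- length(v)
  }
  out <- table
  out$values <- vals
  out <- mark_stage(out, "standardize")
  list(table = out, reference_stats = stats_out)
}

#' Winsorize standardized values
#'
#' Clips standardized values beyond \code{±limit} SD (default 3) to the
#' bound, taming heavy outliers without discarding subjects. Values must
#' already be in SD units (run after [standardize_to_reference()]).
#'
#' @param table a standardized [feature_table()].
#' @param limit positive clip bound in SD units.
#' @return list with the clipped \code{table} and \code{n_clipped}.
#' @export
winsorize <- function(table, limit = 3) {
  stopifnot(inherits(table, "feature_table"))
  check_stage(table, "winsorize")
  if (!is.numeric(limit) || length(limit) != 1 || limit <= 0) stopf("`limit` must be a positive number")
  vals <- table$values
  clip <- !is.na(vals) & abs(vals) > limit
  vals[clip] <- sign(vals[clip]) * limit
  out <- table
  out$values <- vals
  out <- mark_stage(out, "winsorize")
  list(table = out, n_clipped = sum(clip))
}

#' Reverse-code flagged features
#'
#' Negates standardized features whose metadata \code{reverse} flag is set,
#' so that higher values uniformly mean better performance / less impairment
#' (e.g. completion times and error counts are flipped). An involution:
#' applying it twice restores the input.
#'
#' @param table a standardized [feature_table()].
#' @return the table with flagged columns negated.
#' @export
reverse_code <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  done <- stages_done(table)
  if (!"standardize" %in% done) stopf("reverse_code requires standardized values")
  flip <- table$meta$reverse
  out <- table
  out$values[, flip] <- -out$values[, flip, drop = FALSE]
  if ("reverse_code" %in% done) {
    attr(out, "stages") <- setdiff(done, "reverse_code")  # undo = second application
  } else {
    check_stage(out, "reverse_code")
    out <- mark_stage(out, "reverse_code")
  }
  out
}

# Predictor choice for one missing cell: all other features observed in that
# row; if that exceeds a third of the group's rows, keep the 5 most
# correlated with the target (pairwise-complete, within group).
select_predictors <- function(vals, j, obs_row, n_group) {
  cand <- setdiff(which(obs_row), j)
  if (length(cand) > n_group / 3 && length(cand) > 5) {
    cors <- abs(suppressWarnings(stats::cor(vals[, j], vals[, cand, drop = FALSE],
                                            use = "pairwise.complete.obs")))[1, ]
    cors[is.na(cors)] <- -1
    cand <- cand[order(-cors, seq_along(cand))][1:5]
  }
  cand
}

#' Group-wise linear-regression imputation
#'
#' Replaces each missing cell by the ordinary-least-squares prediction of
#' that feature from the other features, fitted on complete-case rows of the
#' same group only (patients and controls are imputed separately, since group
#' differences in the feature means would otherwise bleed across). For each
#' missing cell the predictors are the features observed in that subject's
#' row; when those exceed a third of the group's size, the 5 features most
#' correlated with the target are used. Observed cells are preserved
#' bit-exactly.
#'
#' @param table a [feature_table()] (standardized, winsorized).
#' @return list with the completed \code{table} and \code{n_imputed}.
#' @export
impute_regression <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  check_stage(table, "impute")
  vals <- table$values
  n_imputed <- 0L
  for (g in unique(table$group)) {
    rows <- which(table$group == g)
    gv <- vals[rows, , drop = FALSE]
    for (j in seq_len(ncol(gv))) {
      miss <- which(is.na(gv[, j]))
      if (!length(miss)) next
      if (length(miss) == length(rows)) {
        stopf("feature '%s' is missing for the entire %s group", table$meta$name[j], g)
      }
      for (i in miss) {
        pred <- select_predictors(gv, j, !is.na(gv[i, ]), length(rows))
        cc <- which(!is.na(gv[, j]) & rowSums(is.na(gv[, pred, drop = FALSE])) == 0)
        if (length(cc) < max(5, length(pred) + 2)) {
          stopf("feature '%s' (%s group): only %d complete cases for %d predictors",
                table$meta$name[j], g, length(cc), length(pred))
        }
        X <- cbind(1, gv[cc, pred, drop = FALSE])
        beta <- stats::lm.fit(X, gv[cc, j])$coefficients
        beta[is.na(beta)] <- 0  # collinear predictors contribute nothing
        gv[i, j] <- sum(beta * c(1, gv[i, pred]))
        n_imputed <- n_imputed + 1L
      }
    }
    vals[rows, ] <- gv
  }
  out <- table
  out$values <- vals
  out <- mark_stage(out, "impute")
  list(table = out, n_imputed = n_imputed)
}

#' Residualize age and sex using control-fitted robust regressions
#'
#' For every feature, a robust linear model (Huber M-estimation, tuning
#' constant 1.345, IRLS) \code{value ~ age + sex} is fitted on the healthy
#' controls only; the fitted coefficients are then used to compute residuals
#' for all subjects, patients included. Fitting on controls keeps
#' disease-related variance out of the covariate model while still removing
#' normative age and sex effects from patient scores.
#'
#' @param table a complete (imputed) [feature_table()].
#' @param covariates data frame with columns \code{subject_id}, \code{age}
#'   (years), \code{sex} (0/1 indicator).
#' @return list with the residualized \code{table} and \code{coefficients}
#'   (features x (intercept, age, sex)).
#' @export
residualize_covariates <- function(table, covariates) {
  stopifnot(inherits(table, "feature_table"))
  check_stage(table, "residualize")
  if (anyNA(table$values)) stopf("residualization requires complete data; run impute_regression() first")
  if (!all(c("subject_id", "age", "sex") %in% names(covariates))) {
    stopf("covariates needs columns subject_id, age, sex")
  }
  idx <- match(rownames(table$values), covariates$subject_id)
  if (anyNA(idx)) stopf("covariates missing for subject(s): %s",
                        paste(utils::head(rownames(table$values)[is.na(idx)], 3), collapse = ", "))
  age <- as.numeric(covariates$age[idx])
  sex <- as.numeric(covariates$sex[idx])
  ctrl <- table$group == "control"
  if (sum(ctrl) < 10) stopf("need at least 10 controls to fit the covariate model (have %d)", sum(ctrl))
  if (stats::sd(age[ctrl]) == 0) stopf("age is constant within controls")
  if (length(unique(sex[ctrl])) < 2) stopf("both sexes must be represented in controls")

  vals <- table$values
  coefs <- matrix(NA_real_, ncol(vals), 3,
                  dimnames = list(table$meta$name, c("intercept", "age", "sex")))
  ctrl_df <- data.frame(age = age[ctrl], sex = sex[ctrl])
  for (j in seq_len(ncol(vals))) {
    fit <- MASS::rlm(vals[ctrl, j] ~ age + sex, data = ctrl_df,
                     psi = MASS::psi.huber, k = 1.345, maxit = 200, acc = 1e-8)
    b <- stats::coef(fit)
    coefs[j, ] <- b
    vals[, j] <- vals[, j] - (b[1] + b[2] * age + b[3] * sex)
  }
  out <- table
  out$values <- vals
  out <- mark_stage(out, "residualize")
  list(table = out, coefficients = coefs)
}

#' Mardia's multivariate skewness and kurtosis tests
#'
#' With centered rows \eqn{d_i} and ML covariance \eqn{S} (denominator n),
#' let \eqn{m_{ij} = d_i' S^{-1} d_j}. Mardia's statistics are
#' \eqn{b_{1,p} = n^{-2} \sum_i \sum_j m_{ij}^3} and
#' \eqn{b_{2,p} = n^{-1} \sum_i m_{ii}^2}. Under multivariate normality
#' \eqn{n b_{1,p} / 6} is asymptotically chi-square with
#' \eqn{p(p+1)(p+2)/6} df (upper tail) and
#' \eqn{z = (b_{2,p} - p(p+2)) \sqrt{n / (8 p (p+2))}} is standard normal
#' (two-sided). For p = 1 the statistics reduce to the squared univariate
#' skewness and the univariate kurtosis.
#'
#' @param x numeric matrix, n subjects x p features, complete.
#' @return list: \code{b1p}, \code{b2p}, \code{skew_stat}, \code{skew_df},
#'   \code{skew_p}, \code{kurt_z}, \code{kurt_p}, \code{n}, \code{p}.
#' @export
mardia_tests <- function(x) {
  x <- as_num_matrix(x, "x")
  n <- nrow(x)
  p <- ncol(x)
  if (anyNA(x)) stopf("mardia_tests() requires complete data")
  if (n <= p) stopf("need more subjects than features (n=%d, p=%d)", n, p)
  d <- sweep(x, 2, colMeans(x))
  S <- crossprod(d) / n
  Sinv <- tryCatch(solve(S), error = function(e) stopf("singular covariance matrix"))
  M <- d %*% Sinv %*% t(d)
  b1p <- sum(M^3) / n^2
  b2p <- sum(diag(M)^2) / n
  skew_stat <- n * b1p / 6
  skew_df <- p * (p + 1) * (p + 2) / 6
  kurt_z <- (b2p - p * (p + 2)) * sqrt(n / (8 * p * (p + 2)))
  list(b1p = b1p, b2p = b2p,
       skew_stat = skew_stat, skew_df = skew_df,
       skew_p = stats::pchisq(skew_stat, skew_df, lower.tail = FALSE),
       kurt_z = kurt_z, kurt_p = 2 * stats::pnorm(-abs(kurt_z)),
       n = n, p = p)
}

#' Shapiro-Wilk normality test per feature
#'
#' A univariate normality screen over all features; a standard diagnostic
#' (delegated to [stats::shapiro.test()]). Constant features and features
#' with fewer than 3 non-missing values are reported as non-computable with
#' a warning. Features with more than 5000 non-missing values are tested on
#' a deterministic evenly-spaced subsample of 5000 (the test's supported
#' range).
#'
#' @param table a [feature_table()] or numeric matrix.
#' @return data frame: feature, n, W, p_value (NA where not computable).
#' @export
shapiro_wilk_all <- function(table) {
  vals <- if (inherits(table, "feature_table")) table$values else as_num_matrix(table, "table")
  out <- data.frame(name = colnames(vals) %||% sprintf("f%02d", seq_len(ncol(vals))),
                    n = NA_integer_, W = NA_real_, p_value = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(vals))) {
    v <- vals[, j]
    v <- v[!is.na(v)]
    out$n[j] <- length(v)
    if (length(v) < 3) {
      warning(sprintf("feature '%s': fewer than 3 non-missing values, skipped", out$name[j]))
      next
    }
    if (stats::sd(v) == 0) {
      warning(sprintf("feature '%s': constant values, Shapiro-Wilk not computable", out$name[j]))
      next
    }
    if (length(v) > 5000) v <- v[round(seq(1, length(v), length.out = 5000))]
    sw <- stats::shapiro.test(v)
    out$W[j] <- unname(sw$statistic)
    out$p_value[j] <- sw$p.value
  }
  out
}

#' Run the full preprocessing chain on paired feature tables
#'
#' Applies, in fixed order: optional hemisphere averaging (imaging table),
#' reference standardization, winsorization at \code{±winsor_limit},
#' reverse-coding, group-wise regression imputation and control-fitted
#' robust residualization of age and sex — to both tables, and collects the
#' diagnostics into a report.
#'
#' @param x_table imaging [feature_table()].
#' @param y_table behavioral [feature_table()].
#' @param covariates data frame: subject_id, age, sex.
#' @param winsor_limit winsorization bound in SD units (default 3).
#' @param pairing optional hemisphere pairing for the imaging table
#'   (see [average_hemispheres()]).
#' @return list of class \code{"preprocess_result"}: processed \code{x} and
#'   \code{y} tables and a \code{report} with winsorization/imputation
#'   counts, reference statistics, residualization coefficients, per-feature
#'   Shapiro-Wilk results and Mardia statistics per table.
#' @export
preprocess <- function(x_table, y_table, covariates, winsor_limit = 3, pairing = NULL) {
  stopifnot(inherits(x_table, "feature_table"), inherits(y_table, "feature_table"))
  run_chain <- function(tab) {
    st <- standardize_to_reference(tab)
    wz <- winsorize(st$table, winsor_limit)
    rc <- reverse_code(wz$table)
    im <- impute_regression(rc)
    rz <- residualize_covariates(im$table, covariates)
    list(table = rz$table, ref = st$reference_stats, n_clipped = wz$n_clipped,
         n_imputed = im$n_imputed, coefficients = rz$coefficients)
  }
  if (!is.null(pairing)) x_table <- average_hemispheres(x_table, pairing)
  px <- run_chain(x_table)
  py <- run_chain(y_table)
  report <- list(
    n_winsorized_cells = px$n_clipped + py$n_clipped,
    n_imputed_cells = px$n_imputed + py$n_imputed,
    reference_stats = list(x = px$ref, y = py$ref),
    residualization = list(x = px$coefficients, y = py$coefficients),
    shapiro_wilk = list(x = shapiro_wilk_all(px$table), y = shapiro_wilk_all(py$table)),
    mardia = list(x = mardia_tests(px$table$values[px$table$group == "patient", , drop = FALSE]),
                  y = mardia_tests(py$table$values[py$table$group == "patient", , drop = FALSE])),
    winsor_limit = winsor_limit,
    sex_coding = "0/1 indicator"
  )
  structure(list(x = px$table, y = py$table, report = report),
            class = "preprocess_result")
}
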