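# Synthetic paired-cohort generator with planted canonical structure.
#
# Shared-factor construction: for subject i draw shared latents z ~ N(0, I_m);
# the X-side latent is u_k = z_k and the Y-side latent is
# v_k = rho_k z_k + sqrt(1 - rho_k^2) e_k with independent standard-normal
# e_k, so cor(u_k, v_k) = rho_k exactly and the population canonical
# correlations of the noiseless feature construction equal rho (CCA is
# invariant to the invertible loading maps). Default loading maps are square
# scaled-orthogonal matrices, so the noiseless feature covariance is full
# rank (latent pairs beyond length(rho) are independent, i.e. planted
# correlation 0) and feature-level noise attenuates the planted correlations
# only negligibly.

# Deterministic random orthogonal matrix scaled so each feature carries
# signal variance d (hence noise_sd << sqrt(d) barely attenuates rho).
scaled_ortho <- function(d, seed) {
  with_seed(seed, qr.Q(qr(matrix(stats::rnorm(d * d), d, d))) * sqrt(d))
}

#' Specification of a synthetic paired cohort
#'
#' @param n_patients,n_controls subject counts per group.
#' @param p,q feature counts of the imaging-like (X) and behavioral-like (Y)
#'   tables.
#' @param rho planted canonical correlations, descending, each in \[0, 1),
#'   length m <= min(p, q).
#' @param loadings_x,loadings_y latent-to-feature maps (p x k and q x k with
#'   length(rho) <= k); default square scaled-orthogonal matrices drawn from
#'   the spec seed, so every feature loads on every latent (the correlated,
#'   redundant feature blocks typical of regional imaging and test-battery
#'   data), the noiseless covariance is full rank, and feature noise barely
#'   attenuates the planted correlations.
#' @param noise_sd SD of iid Gaussian feature noise added on top of the
#'   latent signal.
#' @param age_beta,sex_beta per-feature linear covariate effects (length
#'   p + q, X features first; scalars are recycled).
#' @param missing_rate MCAR missingness proportion applied to behavioral (Y)
#'   cells only; the imaging table is generated complete.
#' @param outlier_rate proportion of cells replaced by heavy outliers at
#'   5-8 SD with random sign (so winsorization at ±3 SD provably clips
#'   them).
#' @param patient_shift optional per-feature mean shift added to patients
#'   only (length p + q); controls always follow the unshifted model so the
#'   control sample is a valid standardization reference.
#' @param seed integer; identical seeds give bit-identical cohorts.
#' @return object of class \code{"cca_spec"}.
#' @export
cca_spec <- function(n_patients, n_controls, p, q, rho,
                     loadings_x = NULL, loadings_y = NULL,
                     noise_sd = 0.3, age_beta = 0, sex_beta = 0,
                     missing_rate = 0, outlier_rate = 0,
                     patient_shift = NULL, seed = 1) {
  m <- length(rho)
  if (m > min(p, q)) stopf("length(rho) = %d exceeds min(p, q) = %d", m, min(p, q))
  if (any(rho < 0 | rho >= 1)) stopf("all rho must lie in [0, 1)")
  if (is.unsorted(rev(rho))) stopf("rho must be in descending order")
  if (missing_rate < 0 || missing_rate >= 1) stopf("missing_rate must be in [0, 1)")
  if (outlier_rate < 0 || outlier_rate >= 1) stopf("outlier_rate must be in [0, 1)")
  if (missing_rate + outlier_rate >= 1) stopf("missing_rate + outlier_rate must be < 1")
  if (noise_sd < 0) stopf("noise_sd must be nonnegative")
  if (n_patients < 1 || n_controls < 0) stopf("need n_patients >= 1 and n_controls >= 0")
  if (is.null(loadings_x)) loadings_x <- scaled_ortho(p, seed + 1000003L)
  if (is.null(loadings_y)) loadings_y <- scaled_ortho(q, seed + 2000003L)
  loadings_x <- as.matrix(loadings_x)
  loadings_y <- as.matrix(loadings_y)
  if (nrow(loadings_x) != p || ncol(loadings_x) < m || ncol(loadings_x) > p) {
    stopf("loadings_x must be p x k with %d <= k <= %d", m, p)
  }
  if (nrow(loadings_y) != q || ncol(loadings_y) < m || ncol(loadings_y) > q) {
    stopf("loadings_y must be q x k with %d <= k <= %d", m, q)
  }
  age_beta <- rep_len(age_beta, p + q)
  sex_beta <- rep_len(sex_beta, p + q)
  patient_shift <- rep_len(patient_shift %||% 0, p + q)
  structure(list(n_patients = n_patients, n_controls = n_controls, p = p, q = q,
                 rho = rho, loadings_x = loadings_x, loadings_y = loadings_y,
                 noise_sd = noise_sd, age_beta = age_beta, sex_beta = sex_beta,
                 missing_rate = missing_rate, outlier_rate = outlier_rate,
                 patient_shift = patient_shift, seed = as.integer(seed)),
            class = "cca_spec")
}

#' Generate a synthetic paired cohort with known canonical structure
#'
#' Draws patients and matched controls from the shared-factor model of
#' [cca_spec()]: features are latent signal through the loading maps, plus
#' linear age/sex effects, plus iid Gaussian noise; then MCAR missingness is
#' applied to behavioral cells and heavy outlier cells (5-8 SD, random
#' sign) are injected. Ages are drawn uniformly on 18-65 and sex as a
#' Bernoulli(0.65) indicator, matching in distribution across groups. The
#' generating truth is retained so downstream recovery can be scored.
#'
#' @param spec a [cca_spec()].
#' @param meta_x,meta_y optional feature metadata for the two tables (see
#'   [feature_table()]).
#' @return object of class \code{"synthetic_cohort"}: \code{x_table},
#'   \code{y_table} ([feature_table()]s), \code{covariates} (subject_id,
#'   age, sex, group) and \code{truth} (the spec plus the drawn latents).
#' @export
generate_cohort <- function(spec, meta_x = NULL, meta_y = NULL) {
  stopifnot(inherits(spec, "cca_spec"))
  n <- spec$n_patients + spec$n_controls
  m <- length(spec$rho)
  p <- spec$p
  q <- spec$q
  with_seed(spec$seed, {
    group <- rep(c("patient", "control"), c(spec$n_patients, spec$n_controls))
    age <- stats::runif(n, 18, 65)
    sex <- stats::rbinom(n, 1, 0.65)

    # latent dimensions follow the loading maps; planted rho apply to the
    # leading pairs, later pairs are independent (rho 0)
    mx <- ncol(spec$loadings_x)
    my <- ncol(spec$loadings_y)
    mm <- min(mx, my)
    rho_full <- c(spec$rho, rep(0, mm - m))
    u <- matrix(stats::rnorm(n * mx), n, mx)
    eps <- matrix(stats::rnorm(n * my), n, my)
    v <- eps
    v[, 1:mm] <- sweep(u[, 1:mm, drop = FALSE], 2, rho_full, "*") +
      sweep(eps[, 1:mm, drop = FALSE], 2, sqrt(1 - rho_full^2), "*")

    x <- u %*% t(spec$loadings_x)
    y <- v %*% t(spec$loadings_y)
    if (spec$noise_sd > 0) {
      x <- x + matrix(stats::rnorm(n * p, sd = spec$noise_sd), n, p)
      y <- y + matrix(stats::rnorm(n * q, sd = spec$noise_sd), n, q)
    }
    x <- x + outer(age, spec$age_beta[1:p]) + outer(sex, spec$sex_beta[1:p])
    y <- y + outer(age, spec$age_beta[p + 1:q]) + outer(sex, spec$sex_beta[p + 1:q])
    pat <- group == "patient"
    x[pat, ] <- sweep(x[pat, , drop = FALSE], 2, spec$patient_shift[1:p], "+")
    y[pat, ] <- sweep(y[pat, , drop = FALSE], 2, spec$patient_shift[p + 1:q], "+")

    if (spec$outlier_rate > 0) {
      inject <- function(mat) {
        cells <- which(stats::runif(length(mat)) < spec$outlier_rate)
        if (length(cells)) {
          col_sd <- apply(mat, 2, stats::sd)
          col_mu <- colMeans(mat)
          cols <- (cells - 1) %/% nrow(mat) + 1
          mag <- stats::runif(length(cells), 5, 8)
          sgn <- sample(c(-1, 1), length(cells), replace = TRUE)
          mat[cells] <- col_mu[cols] + sgn * mag * col_sd[cols]
        }
        mat
      }
      x <- inject(x)
      y <- inject(y)
    }
    if (spec$missing_rate > 0) {
      drop_cells <- which(stats::runif(length(y)) < spec$missing_rate)
      y[drop_cells] <- NA_real_
    }

    ids <- sprintf("S%04d", seq_len(n))
    rownames(x) <- rownames(y) <- ids
    colnames(x) <- if (!is.null(meta_x)) meta_x$name else sprintf("img%02d", 1:p)
    colnames(y) <- if (!is.null(meta_y)) meta_y$name else sprintf("beh%02d", 1:q)
    if (is.null(meta_x)) {
      meta_x <- data.frame(name = colnames(x), modality = "structural",
                           reverse = FALSE, reference = "control",
                           stringsAsFactors = FALSE)
    }
    structure(list(
      x_table = feature_table(x, group, meta_x),
      y_table = feature_table(y, group, meta_y),
      covariates = data.frame(subject_id = ids, age = age, sex = sex,
                              group = group, stringsAsFactors = FALSE),
      truth = list(spec = spec, u = u, v = v)
    ), class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  s <- x$truth$spec
  cat(sprintf("synthetic_cohort: %d patients + %d controls; p = %d, q = %d\n",
              s$n_patients, s$n_controls, s$p, s$q))
  cat(sprintf("  planted rho: %s; noise_sd = %.2f; missing %.3f, outliers %.3f (seed %d)\n",
              paste(sprintf("%.2f", s$rho), collapse = ", "), s$noise_sd,
              s$missing_rate, s$outlier_rate, s$seed))
  invisible(x)
}

#' Write a synthetic cohort to delimited files
#'
#' Writes x.csv, y.csv (subject_id, group, then features), covariates.csv,
#' meta_x.csv / meta_y.csv and a truth.json with the generating parameters.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if absent).
#' @return invisibly, the written file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(tab, path) {
    df <- data.frame(subject_id = rownames(tab$values), group = tab$group,
                     tab$values, check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE)
    path
  }
  paths <- c(
    wt(cohort$x_table, file.path(dir, "x.csv")),
    wt(cohort$y_table, file.path(dir, "y.csv")))
  utils::write.csv(cohort$covariates, file.path(dir, "covariates.csv"), row.names = FALSE)
  utils::write.csv(cohort$x_table$meta, file.path(dir, "meta_x.csv"), row.names = FALSE)
  utils::write.csv(cohort$y_table$meta, file.path(dir, "meta_y.csv"), row.names = FALSE)
  s <- cohort$truth$spec
  truth <- s[c("n_patients", "n_controls", "p", "q", "rho", "noise_sd",
               "missing_rate", "outlier_rate", "seed")]
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(c(paths, file.path(dir, c("covariates.csv", "meta_x.csv", "meta_y.csv", "truth.json"))))
}

#' Read a feature table written by [write_cohort()]
#'
#' @param path CSV with columns subject_id, group, then features.
#' @param meta_path optional feature-metadata CSV (name, modality, reverse,
#'   reference).
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path, meta_path = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "group") %in% names(df)[1:2])) {
    stopf("expected first columns subject_id, group in %s", path)
  }
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(vals) <- df$subject_id
  meta <- if (!is.null(meta_path)) utils::read.csv(meta_path, stringsAsFactors = FALSE)
  feature_table(vals, df$group, meta)
}

#' Generate synthetic resting-state network data with known mixing
#'
#' Each subject's voxels x timepoints matrix is
#' \code{t(group_maps) %*% timeseries + noise}, where the component time
#' series are drawn multivariate normal with the requested cross-correlation
#' structure. The generating truth is retained so dual-regression recovery
#' can be scored.
#'
#' @param n_subjects subject count.
#' @param n_voxels,n_time voxels and timepoints per subject.
#' @param group_maps components x voxels matrix of group spatial maps
#'   (rows must be linearly independent).
#' @param true_timeseries_corr components x components correlation matrix of
#'   the underlying time series (symmetric positive-definite, unit
#'   diagonal).
#' @param noise_sd SD of iid voxel noise.
#' @param seed integer seed.
#' @return object of class \code{"rsn_data"}: \code{group_maps},
#'   \code{subject_data} (list of voxels x time matrices),
#'   \code{network_labels}, and \code{truth} (per-subject time series).
#' @export
generate_rsn_data <- function(n_subjects, n_voxels, n_time, group_maps,
                              true_timeseries_corr, noise_sd = 0.5, seed = 1) {
  group_maps <- as_num_matrix(group_maps, "group_maps")
  m <- nrow(group_maps)
  if (ncol(group_maps) != n_voxels) stopf("group_maps must have %d columns (voxels)", n_voxels)
  if (qr(group_maps)$rank < m) stopf("group_maps rows must be linearly independent")
  C <- as_num_matrix(true_timeseries_corr, "true_timeseries_corr")
  if (!isTRUE(all.equal(C, t(C))) || any(abs(diag(C) - 1) > 1e-8)) {
    stopf("true_timeseries_corr must be symmetric with unit diagonal")
  }
  ch <- tryCatch(chol(C), error = function(e) stopf("true_timeseries_corr is not positive-definite"))
  with_seed(seed, {
    subject_data <- vector("list", n_subjects)
    truth_ts <- vector("list", n_subjects)
    for (s in seq_len(n_subjects)) {
      ts <- t(ch) %*% matrix(stats::rnorm(m * n_time), m, n_time)
      dat <- t(group_maps) %*% ts
      if (noise_sd > 0) dat <- dat + matrix(stats::rnorm(n_voxels * n_time, sd = noise_sd), n_voxels, n_time)
      subject_data[[s]] <- dat
      truth_ts[[s]] <- ts
    }
    structure(list(group_maps = group_maps, subject_data = subject_data,
                   network_labels = rownames(group_maps) %||% sprintf("RSN%d", 1:m),
                   truth = list(timeseries = truth_ts, corr = C, seed = seed)),
              class = "rsn_data")
  })
}

#' Generate framewise-displacement series with exact requested means
#'
#' Draws nonnegative per-timepoint head-motion series (absolute Gaussian
#' draws) rescaled so each subject's mean equals the requested value to
#' within numerical precision; a requested mean of 0 gives an all-zero
#' series.
#'
#' @param mean_fd_values nonnegative per-subject target means (mm).
#' @param n_time timepoints per series.
#' @param seed integer seed.
#' @return list of numeric series, one per subject.
#' @export
generate_fd_series <- function(mean_fd_values, n_time, seed = 1) {
  if (any(mean_fd_values < 0)) stopf("mean FD values must be nonnegative")
  with_seed(seed, {
    lapply(mean_fd_values, function(mu) {
      if (mu == 0) return(rep(0, n_time))
      raw <- abs(stats::rnorm(n_time, mean = 1, sd = 0.4))
      raw * (mu / mean(raw))
    })
  })
}
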