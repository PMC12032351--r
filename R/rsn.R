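# Dual regression and resting-state network summary metrics.

#' Exclude high-motion subjects by mean framewise displacement
#'
#' A subject is excluded iff the mean of their framewise-displacement series
#' strictly exceeds the threshold (default 0.2 mm); a mean exactly at the
#' threshold is retained.
#'
#' @param fd list of nonnegative per-subject FD series (mm).
#' @param threshold exclusion cut-off on the series mean.
#' @return list with integer vectors \code{retained} and \code{excluded} and
#'   the per-subject \code{mean_fd}.
#' @export
exclude_high_motion <- function(fd, threshold = 0.2) {
  if (!length(fd)) stopf("empty FD input")
  mean_fd <- vapply(fd, function(s) {
    if (!length(s)) stopf("empty FD series")
    if (any(s < 0)) stopf("FD series must be nonnegative")
    mean(s)
  }, numeric(1))
  excl <- which(mean_fd > threshold)
  list(retained = setdiff(seq_along(fd), excl), excluded = excl,
       mean_fd = mean_fd, threshold = threshold)
}

#' Dual regression of subject data on group spatial maps
#'
#' Two multivariate least-squares steps per subject. Step 1 (spatial
#' regression): each timepoint's voxel vector is regressed on all group maps
#' simultaneously, yielding the subject-specific time series of every
#' component while controlling for the others. Step 2 (temporal regression):
#' each voxel's time course is regressed on the variance-normalized time
#' series, yielding subject-specific spatial parameter-estimate (PE) maps
#' whose units are comparable across subjects.
#'
#' @param group_maps components x voxels matrix; rows linearly independent.
#' @param subject_data voxels x timepoints matrix for one subject, or a list
#'   of such matrices (or an [generate_rsn_data()] object).
#' @return for one subject, list with \code{timeseries} (components x
#'   timepoints, raw scale) and \code{pe_maps} (components x voxels); for a
#'   list input, a list of such results.
#' @export
dual_regression <- function(group_maps, subject_data) {
  if (inherits(group_maps, "rsn_data")) {
    dat <- group_maps
    return(lapply(dat$subject_data, function(d) dual_regression(dat$group_maps, d)))
  }
  group_maps <- as_num_matrix(group_maps, "group_maps")
  if (is.list(subject_data)) {
    return(lapply(subject_data, function(d) dual_regression(group_maps, d)))
  }
  d <- as_num_matrix(subject_data, "subject_data")
  m <- nrow(group_maps)
  n_vox <- ncol(group_maps)
  if (nrow(d) != n_vox) stopf("subject data has %d voxels but maps have %d", nrow(d), n_vox)
  if (m >= n_vox) stopf("need fewer components than voxels")
  if (ncol(d) <= m) stopf("need more timepoints than components")
  A <- t(group_maps)                       # voxels x m spatial design
  if (qr(A)$rank < m) stopf("rank-deficient spatial design (collinear group maps)")
  ts <- qr.solve(A, d)                     # m x time
  sds <- apply(ts, 1, stats::sd)
  if (any(sds == 0)) stopf("constant recovered time series for component %d", which(sds == 0)[1])
  B <- t(ts / sds)                         # time x m, unit-variance regressors
  if (qr(B)$rank < m) stopf("rank-deficient temporal design")
  pe <- qr.solve(B, t(d))                  # m x voxels
  rownames(ts) <- rownames(pe) <- rownames(group_maps)
  list(timeseries = ts, pe_maps = pe)
}

#' Network integrity: mean PE over each network's voxels
#'
#' Within-network connectivity strength: the arithmetic mean of a subject's
#' parameter estimates across the voxels belonging to each network.
#'
#' @param pe_maps components x voxels PE matrix from [dual_regression()].
#' @param network_masks list (one element per network) of voxel indices or a
#'   logical vector over voxels; defaults to voxels where that network's
#'   group map exceeds \code{mask_z}.
#' @param group_maps needed only when \code{network_masks} is NULL.
#' @param mask_z z threshold defining a network's voxel set from its group
#'   map (default 3).
#' @return named numeric vector, one integrity value per network.
#' @export
network_integrity <- function(pe_maps, network_masks = NULL, group_maps = NULL,
                              mask_z = 3) {
  pe_maps <- as_num_matrix(pe_maps, "pe_maps")
  m <- nrow(pe_maps)
  if (is.null(network_masks)) {
    if (is.null(group_maps)) stopf("supply network_masks or group_maps")
    network_masks <- lapply(seq_len(m), function(k) which(group_maps[k, ] > mask_z))
  }
  if (length(network_masks) != m) stopf("need one mask per component (%d)", m)
  out <- vapply(seq_len(m), function(k) {
    mask <- network_masks[[k]]
    if (is.logical(mask)) mask <- which(mask)
    if (!length(mask)) stopf("empty voxel mask for network %d", k)
    if (any(mask < 1 | mask > ncol(pe_maps))) stopf("mask for network %d outside voxel range", k)
    mean(pe_maps[k, mask])
  }, numeric(1))
  names(out) <- rownames(pe_maps) %||% sprintf("RSN%d", seq_len(m))
  out
}

#' Network segregation: Fisher-z between-network correlations
#'
#' Between-network connectivity: Pearson correlation of each pair of
#' component time series, Fisher-transformed (\eqn{z = atanh(r)}) to
#' stabilize the scale. Perfectly correlated series (|r| = 1) put atanh at
#' its pole; the value is capped at atanh(1 - 1e-15) with a warning.
#'
#' @param timeseries components x timepoints matrix from step 1 of
#'   [dual_regression()].
#' @return symmetric components x components matrix of Fisher-z values with
#'   NA diagonal.
#' @export
network_segregation <- function(timeseries) {
  ts <- as_num_matrix(timeseries, "timeseries")
  if (ncol(ts) < 3) stopf("need at least 3 timepoints")
  sds <- apply(ts, 1, stats::sd)
  if (any(sds == 0)) {
    stopf("constant time series for network %s",
          (rownames(ts) %||% seq_len(nrow(ts)))[which(sds == 0)[1]])
  }
  r <- stats::cor(t(ts))
  if (any(abs(r[upper.tri(r)]) >= 1 - 1e-15)) {
    warning("perfectly correlated time series: Fisher z capped")
    r <- pmin(pmax(r, -(1 - 1e-15)), 1 - 1e-15)
  }
  z <- atanh(r)
  diag(z) <- NA_real_
  dimnames(z) <- list(rownames(ts), rownames(ts))
  z
}

#' Compute all RSN metrics for a cohort
#'
#' Applies motion exclusion, dual regression, integrity and segregation to
#' every retained subject.
#'
#' @param rsn an [generate_rsn_data()] object (or list with
#'   \code{group_maps} and \code{subject_data}).
#' @param fd optional list of FD series aligned with subjects.
#' @param fd_threshold mean-FD exclusion cut-off (default 0.2).
#' @param mask_z group-map z threshold defining integrity masks (default 3).
#' @return object of class \code{"rsn_metrics"}: \code{integrity} (subjects
#'   x networks), \code{segregation} (list of Fisher-z matrices),
#'   \code{timeseries}, \code{pe_maps}, \code{excluded_subjects}.
#' @export
rsn_metrics <- function(rsn, fd = NULL, fd_threshold = 0.2, mask_z = 3) {
  maps <- rsn$group_maps
  subjects <- seq_along(rsn$subject_data)
  excluded <- integer(0)
  mean_fd <- NULL
  if (!is.null(fd)) {
    part <- exclude_high_motion(fd, fd_threshold)
    excluded <- part$excluded
    subjects <- part$retained
    mean_fd <- part$mean_fd
  }
  masks <- lapply(seq_len(nrow(maps)), function(k) which(maps[k, ] > mask_z))
  dr <- lapply(subjects, function(s) dual_regression(maps, rsn$subject_data[[s]]))
  integ <- t(vapply(dr, function(r) network_integrity(r$pe_maps, masks), numeric(nrow(maps))))
  rownames(integ) <- subjects
  segr <- lapply(dr, function(r) network_segregation(r$timeseries))
  names(segr) <- subjects
  structure(list(integrity = integ, segregation = segr,
                 timeseries = lapply(dr, `[[`, "timeseries"),
                 pe_maps = lapply(dr, `[[`, "pe_maps"),
                 retained_subjects = subjects,
                 excluded_subjects = excluded, mean_fd = mean_fd,
                 mask_z = mask_z, fd_threshold = fd_threshold),
            class = "rsn_metrics")
}

#' @export
print.rsn_metrics <- function(x, ...) {
  cat(sprintf("rsn_metrics: %d subjects retained, %d excluded (mean FD > %.2f)\n",
              length(x$retained_subjects), length(x$excluded_subjects), x$fd_threshold))
  cat(sprintf("  networks: %s\n", paste(colnames(x$integrity), collapse = ", ")))
  invisible(x)
}
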