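#' Canonical correlation analysis
#'
#' Fits classical canonical correlation analysis (CCA) between two
#' subject-by-feature matrices. CCA finds paired linear combinations
#' (canonical variates) \eqn{u_k = X a_k}, \eqn{v_k = Y b_k} that maximize
#' the Pearson correlation \eqn{r_k = cor(u_k, v_k)}, with successive pairs
#' uncorrelated with earlier ones. The solution is obtained by singular value
#' decomposition of the whitened cross-covariance
#' \eqn{\Sigma_{xx}^{-1/2} \Sigma_{xy} \Sigma_{yy}^{-1/2}}, using symmetric
#' inverse square roots with an eigenvalue floor of \code{1e-12 * trace} for
#' numerical stability (rank deficiency below the floor is an error, not
#' silently regularized).
#'
#' Sign indeterminacy of each variate pair is resolved deterministically: the
#' X-side loading of largest absolute value is made positive (both weight
#' vectors of the pair are flipped together, so canonical correlations stay
#' nonnegative).
#'
#' @param x numeric matrix or data frame, n subjects by p features.
#' @param y numeric matrix or data frame, n subjects by q features.
#' @return An object of class \code{"cca_fit"} with components:
#'   \item{r}{canonical correlations, descending, length \code{min(p, q)}.}
#'   \item{wx, wy}{p x m and q x m canonical weight matrices.}
#'   \item{u, v}{n x m centered, unit-variance canonical variate scores.}
#'   \item{loadings_x, loadings_y}{correlations of each feature with the
#'     variates of its own set.}
#'   \item{cross_x, cross_y}{correlations of each feature with the variates
#'     of the other set.}
#'   \item{wilks}{data frame of sequential Wilks' lambda tests
#'     (see [wilks_tests()]).}
#'   \item{centers_x, centers_y}{column means used for centering, needed to
#'     project new data via [predict.cca_fit()].}
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200), 50, 4)
#' y <- x[, 1:2] + matrix(rnorm(100, sd = 0.5), 50, 2)
#' fit <- cca_fit(x, y)
#' fit$r
#' summary(fit)
#' @seealso [permutation_test()], [cross_validate()], [wilks_tests()]
#' @export
cca_fit <- function(x, y) {
  x <- as_num_matrix(x, "x")
  y <- as_num_matrix(y, "y")
  n <- nrow(x)
  p <- ncol(x)
  q <- ncol(y)
  if (nrow(y) != n) stopf("x and y must have the same number of rows (%d vs %d)", n, nrow(y))
  if (anyNA(x) || anyNA(y)) stopf("cca_fit() requires complete data; impute missing values first")
  if (n <= p + q) stopf("need n > p + q subjects (n=%d, p=%d, q=%d); no regularization fallback", n, p, q)
  sd_x <- apply(x, 2, stats::sd)
  sd_y <- apply(y, 2, stats::sd)
  if (any(sd_x == 0)) stopf("constant column in x: %s", colnames(x)[which(sd_x == 0)[1]] %||% which(sd_x == 0)[1])
  if (any(sd_y == 0)) stopf("constant column in y: %s", colnames(y)[which(sd_y == 0)[1]] %||% which(sd_y == 0)[1])

  cx <- colMeans(x)
  cy <- colMeans(y)
  xc <- sweep(x, 2, cx)
  yc <- sweep(y, 2, cy)
  sxx <- crossprod(xc) / (n - 1)
  syy <- crossprod(yc) / (n - 1)
  sxy <- crossprod(xc, yc) / (n - 1)

  kx <- inv_sqrt_sym(sxx, "x")
  ky <- inv_sqrt_sym(syy, "y")
  sv <- svd(kx %*% sxy %*% ky)
  m <- min(p, q)
  r <- pmin(pmax(sv$d[seq_len(m)], 0), 1)
  wx <- kx %*% sv$u[, seq_len(m), drop = FALSE]
  wy <- ky %*% sv$v[, seq_len(m), drop = FALSE]

  u <- xc %*% wx
  v <- yc %*% wy
  loadings_x <- stats::cor(x, u)
  # sign convention: dominant X loading positive per pair
  for (k in seq_len(m)) {
    j <- which.max(abs(loadings_x[, k]))
    if (loadings_x[j, k] < 0) {
      wx[, k] <- -wx[, k]
      wy[, k] <- -wy[, k]
      u[, k] <- -u[, k]
      v[, k] <- -v[, k]
      loadings_x[, k] <- -loadings_x[, k]
    }
  }
  loadings_y <- stats::cor(y, v)
  cross_x <- stats::cor(x, v)
  cross_y <- stats::cor(y, u)

  dn <- function(mat, rn, base) {
    rownames(mat) <- rn %||% paste0(base, seq_len(nrow(mat)))
    colnames(mat) <- paste0("CV", seq_len(ncol(mat)))
    mat
  }
  fit <- structure(list(
    r = r,
    wx = dn(wx, colnames(x), "x"), wy = dn(wy, colnames(y), "y"),
    u = u, v = v,
    loadings_x = dn(loadings_x, colnames(x), "x"),
    loadings_y = dn(loadings_y, colnames(y), "y"),
    cross_x = dn(cross_x, colnames(x), "x"),
    cross_y = dn(cross_y, colnames(y), "y"),
    wilks = wilks_tests(r, n, p, q),
    centers_x = cx, centers_y = cy,
    n = n, p = p, q = q,
    call = match.call()
  ), class = "cca_fit")
  fit
}

#' Sequential Wilks' lambda tests of canonical correlations
#'
#' Tests, for each k, the null hypothesis that canonical pairs k..m carry no
#' association: \eqn{\Lambda_k = \prod_{i=k}^{m} (1 - r_i^2)}. Significance
#' uses Rao's F approximation (the convention of mainstream CCA software);
#' Bartlett's chi-square statistic is reported as a secondary column. For
#' univariate sets (p = q = 1) Rao's F reduces exactly to the F test of a
#' Pearson correlation, \eqn{F = r^2 (n-2) / (1 - r^2)} on (1, n-2) df.
#'
#' @param r canonical correlations, descending, in \[0, 1\].
#' @param n number of subjects.
#' @param p,q numbers of features in the two sets.
#' @return data frame with one row per pair: \code{lambda}, \code{F},
#'   \code{df1}, \code{df2}, \code{p_value}, \code{chisq}, \code{chisq_df},
#'   \code{chisq_p}.
#' @export
wilks_tests <- function(r, n, p, q) {
  m <- min(p, q)
  if (length(r) != m) stopf("expected %d canonical correlations, got %d", m, length(r))
  if (is.unsorted(rev(r))) stopf("canonical correlations must be descending")
  if (any(r < 0 | r > 1)) stopf("canonical correlations must lie in [0, 1]")
  if (n <= p + q) stopf("Wilks tests require n > p + q")
  if (any(r == 1)) warning("canonical correlation of exactly 1: Wilks' lambda is 0, p below machine precision")

  out <- data.frame(pair = seq_len(m), lambda = NA_real_, F = NA_real_,
                    df1 = NA_real_, df2 = NA_real_, p_value = NA_real_,
                    chisq = NA_real_, chisq_df = NA_real_, chisq_p = NA_real_)
  for (k in seq_len(m)) {
    lam <- prod(1 - r[k:m]^2)
    pk <- p - k + 1
    qk <- q - k + 1
    rr <- (n - 1) - (pk + qk + 1) / 2
    uu <- (pk * qk - 2) / 4
    tt <- if (pk^2 + qk^2 - 5 > 0) sqrt((pk^2 * qk^2 - 4) / (pk^2 + qk^2 - 5)) else 1
    df1 <- pk * qk
    df2 <- rr * tt - 2 * uu
    lam_t <- lam^(1 / tt)
    Fstat <- if (lam > 0) ((1 - lam_t) / lam_t) * (df2 / df1) else Inf
    out$lambda[k] <- lam
    out$F[k] <- Fstat
    out$df1[k] <- df1
    out$df2[k] <- df2
    out$p_value[k] <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
    # Bartlett's chi-square, secondary
    out$chisq[k] <- if (lam > 0) -(n - 1 - (p + q + 1) / 2) * log(lam) else Inf
    out$chisq_df[k] <- pk * qk
    out$chisq_p[k] <- stats::pchisq(out$chisq[k], out$chisq_df[k], lower.tail = FALSE)
  }
  out
}

#' Loadings and cross-loadings of a fitted CCA
#'
#' Loadings are Pearson correlations between each feature and the canonical
#' variate of its own set; cross-loadings correlate each feature with the
#' variate of the other set. Cross-loadings are the quantity that most
#' directly expresses which features of one set track the other set's
#' pattern.
#'
#' @param fit a \code{"cca_fit"} object.
#' @param x,y the data matrices the model was fitted to.
#' @return list with \code{loadings_x}, \code{loadings_y}, \code{cross_x},
#'   \code{cross_y}.
#' @export
compute_loadings <- function(fit, x, y) {
  stopifnot(inherits(fit, "cca_fit"))
  x <- as_num_matrix(x, "x")
  y <- as_num_matrix(y, "y")
  if (nrow(x) != nrow(fit$u) || ncol(x) != fit$p || ncol(y) != fit$q) {
    stopf("data dimensions do not match the fitted model (n=%d, p=%d, q=%d)", nrow(fit$u), fit$p, fit$q)
  }
  list(loadings_x = stats::cor(x, fit$u), loadings_y = stats::cor(y, fit$v),
       cross_x = stats::cor(x, fit$v), cross_y = stats::cor(y, fit$u))
}

#' Flag substantial loadings
#'
#' A loading or cross-loading is substantial when its absolute value strictly
#' exceeds the threshold (default 0.3, the conventional cut-off for
#' interpreting canonical structure).
#'
#' @param loadings numeric matrix of values in \[-1, 1\].
#' @param threshold positive scalar in (0, 1).
#' @return logical matrix of the same shape.
#' @export
flag_substantial <- function(loadings, threshold = 0.3) {
  loadings <- as_num_matrix(loadings, "loadings")
  if (any(abs(loadings) > 1 + 1e-8, na.rm = TRUE)) stopf("loadings must lie in [-1, 1]")
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) stopf("`threshold` must be in (0, 1)")
  abs(loadings) > threshold
}

#' @export
print.cca_fit <- function(x, ...) {
  cat("Canonical correlation analysis\n")
  cat(sprintf("  n = %d subjects, p = %d x-features, q = %d y-features\n", x$n, x$p, x$q))
  cat("  canonical correlations:", paste(sprintf("%.3f", x$r), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.cca_fit <- function(object, threshold = 0.3, ...) {
  res <- list(fit = object, threshold = threshold,
              substantial_x = flag_substantial(object$loadings_x, threshold),
              substantial_y = flag_substantial(object$loadings_y, threshold))
  class(res) <- "summary.cca_fit"
  res
}

#' @export
print.summary.cca_fit <- function(x, ...) {
  print(x$fit)
  cat("\nSequential Wilks' lambda tests (Rao's F):\n")
  print(format(x$fit$wilks[, c("pair", "lambda", "F", "df1", "df2", "p_value")], digits = 3),
        row.names = FALSE)
  n_sub <- sum(x$substantial_x[, 1]) + sum(x$substantial_y[, 1])
  cat(sprintf("\nFirst pair: %d features with |loading| > %.2f\n", n_sub, x$threshold))
  invisible(x)
}

#' @export
coef.cca_fit <- function(object, ...) list(wx = object$wx, wy = object$wy)

#' Project new data onto fitted canonical weights
#'
#' Applies the training centering and weights to new rows, returning variate
#' scores. Used internally by cross-validation to score held-out folds.
#'
#' @param object a \code{"cca_fit"} object.
#' @param newx,newy new data matrices with the fitted feature counts.
#' @param ... unused.
#' @return list with matrices \code{u} and \code{v} (whichever of
#'   \code{newx}/\code{newy} was supplied).
#' @export
predict.cca_fit <- function(object, newx = NULL, newy = NULL, ...) {
  out <- list()
  if (!is.null(newx)) {
    newx <- as_num_matrix(newx, "newx")
    if (ncol(newx) != object$p) stopf("newx must have %d columns", object$p)
    out$u <- sweep(newx, 2, object$centers_x) %*% object$wx
  }
  if (!is.null(newy)) {
    newy <- as_num_matrix(newy, "newy")
    if (ncol(newy) != object$q) stopf("newy must have %d columns", object$q)
    out$v <- sweep(newy, 2, object$centers_y) %*% object$wy
  }
  out
}

#' @export
plot.cca_fit <- function(x, pair = 1, ...) {
  plot(x$u[, pair], x$v[, pair],
       xlab = sprintf("imaging variate %d", pair),
       ylab = sprintf("behavioral variate %d", pair),
       main = sprintf("Canonical pair %d (r = %.2f)", pair, x$r[pair]), ...)
  graphics::abline(stats::lm(x$v[, pair] ~ x$u[, pair]), col = "red3")
  invisible(x)
}
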