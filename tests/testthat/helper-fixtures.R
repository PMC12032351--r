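# Shared fixtures, all generated in code under explicit seeds.

# Paired matrices with planted canonical correlations, patients only,
# no covariate effects / missingness / outliers.
planted_xy <- function(n, p, q, rho, noise_sd = 0.3, seed = 1) {
  spec <- cca_spec(n_patients = n, n_controls = 0, p = p, q = q, rho = rho,
                   noise_sd = noise_sd, seed = seed)
  co <- generate_cohort(spec)
  list(x = co$x_table$values, y = co$y_table$values, truth = co$truth)
}

# Independent-oracle CCA r1: direct generalized-eigenvalue solve of
# Sxx^-1 Sxy Syy^-1 Syx (dense eigen solver, no whitening path shared with
# the implementation).
geneig_r1 <- function(x, y) {
  xc <- scale(x, scale = FALSE)
  yc <- scale(y, scale = FALSE)
  n <- nrow(x)
  sxx <- crossprod(xc) / (n - 1)
  syy <- crossprod(yc) / (n - 1)
  sxy <- crossprod(xc, yc) / (n - 1)
  M <- solve(sxx, sxy) %*% solve(syy, t(sxy))
  sqrt(max(Re(eigen(M, only.values = TRUE)$values)))
}

# Brute-force oracle for p = q = 2: maximize cor(x a, y b) over unit weight
# vectors on an angular grid of the given resolution (degrees).
grid_r1 <- function(x, y, step_deg = 1) {
  ang <- seq(0, 180 - step_deg, by = step_deg) * pi / 180
  best <- 0
  for (a in ang) {
    u <- x %*% c(cos(a), sin(a))
    for (b in ang) {
      v <- y %*% c(cos(b), sin(b))
      best <- max(best, abs(stats::cor(u, v)))
    }
  }
  best
}

# Small raw two-group feature table for preprocessing tests.
make_table <- function(n_pat = 30, n_ctrl = 20, p = 4, seed = 1,
                       modality = "cognitive", reverse = FALSE,
                       reference = "control") {
  set.seed(seed)
  n <- n_pat + n_ctrl
  vals <- matrix(rnorm(n * p, mean = 10, sd = 2), n, p,
                 dimnames = list(sprintf("S%03d", 1:n), sprintf("f%02d", 1:p)))
  meta <- data.frame(name = colnames(vals), modality = modality,
                     reverse = rep_len(reverse, p),
                     reference = rep_len(reference, p), stringsAsFactors = FALSE)
  feature_table(vals, rep(c("patient", "control"), c(n_pat, n_ctrl)), meta)
}

make_covariates <- function(table, seed = 1) {
  set.seed(seed)
  n <- nrow(table$values)
  data.frame(subject_id = rownames(table$values),
             age = runif(n, 20, 60), sex = rbinom(n, 1, 0.5),
             stringsAsFactors = FALSE)
}

# Marks a table as standardized without changing values (for unit tests of
# later stages on hand-constructed z-scale data).
mark_standardized <- function(table) {
  attr(table, "stages") <- c(attr(table, "stages"), "standardize")
  table
}
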