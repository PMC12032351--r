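# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never disturb the
# global stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

as_num_matrix <- function(x, arg = deparse(substitute(x))) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stopf("`%s` must be a numeric matrix", arg)
  storage.mode(x) <- "double"
  x
}

# Symmetric inverse square root with an eigenvalue floor relative to the
# trace; fails loudly on effective rank deficiency.
inv_sqrt_sym <- function(S, label, floor_rel = 1e-12) {
  ee <- eigen(S, symmetric = TRUE)
  floor_abs <- floor_rel * sum(diag(S))
  if (any(ee$values < floor_abs)) {
    stopf("covariance of the %s set is (near-)rank-deficient: smallest eigenvalue %.3e below floor %.3e",
          label, min(ee$values), floor_abs)
  }
  ee$vectors %*% (t(ee$vectors) / sqrt(ee$values))
}
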