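`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a root seed
#'
#' All stages of the pipeline draw their randomness from substreams derived
#' deterministically from one root seed, so stages can be re-run in
#' isolation. Result always fits a 32-bit integer.
#'
#' @param seed integer root seed.
#' @param offset integer substream index (>= 0).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, offset = 0L) {
  s <- (abs(as.numeric(seed)) %% 1000003) * 2017 + as.numeric(offset) * 7919
  as.integer(s %% 2147483647) + 1L
}

# symmetric PSD square root (tolerates singular matrices, e.g. zero CVs)
mat_sqrt_psd <- function(S, tol = 1e-8) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  lo <- min(e$values)
  if (lo < -tol * max(abs(e$values), 1))
    stop("matrix is not positive semi-definite (min eigenvalue ", signif(lo, 3), ")")
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

# n draws from N(mu, Sigma); rows are observations
rmvnorm_psd <- function(n, mu, Sigma) {
  R <- mat_sqrt_psd(Sigma)
  Z <- matrix(rnorm(n * length(mu)), nrow = n)
  sweep(Z %*% R, 2, mu, `+`)
}

assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

col_sds <- function(X) apply(X, 2, sd)

# md5 of an R object via its serialized JSON (used to stamp output files)
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE), f)
  unname(tools::md5sum(f))
}
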