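# Spectral and tabular pretreatments. Row-wise operators (SNV, MSC, SavGol,
# trimming) act on spectra_block or plain matrices; column-wise operators
# (mean centering, autoscaling, block scaling) carry their fitted statistics
# as attributes so test data are always transformed with training statistics.

with_block <- function(x, f) {
  if (inherits(x, "spectra_block")) {
    x$X <- f(x$X)
    x
  } else f(as.matrix(x))
}

get_X <- function(x) if (inherits(x, "spectra_block")) x$X else as.matrix(x)

#' Trim a spectra block to a wavenumber range
#'
#' Retains columns whose wavenumber lies in the closed interval
#' `[low, high]`, preserving order; the informative default analysis range
#' is 9000-4000 cm-1.
#'
#' @param block a [spectra_block()].
#' @param low,high range bounds in cm-1 (`high > low`).
#' @return trimmed `spectra_block`.
#' @export
trim_range <- function(block, low = 4000, high = 9000) {
  assert_that(high > low, "high must exceed low")
  keep <- block$grid >= low & block$grid <= high
  if (!any(keep))
    stop(sprintf("no grid points in [%g, %g]; grid spans [%g, %g]",
                 low, high, min(block$grid), max(block$grid)), call. = FALSE)
  block$X <- block$X[, keep, drop = FALSE]
  block$grid <- block$grid[keep]
  block
}

#' Standard normal variate transform
#'
#' Each row is standardized to mean 0, standard deviation 1 (sample sd,
#' divisor n-1). Removes multiplicative and additive scatter per spectrum.
#'
#' @param x a `spectra_block` or matrix.
#' @return object of the same kind.
#' @export
snv <- function(x) {
  with_block(x, function(X) {
    mu <- rowMeans(X)
    s <- apply(X, 1, sd)
    zero <- which(s == 0)
    if (length(zero))
      stop("constant row(s), SNV undefined: ", paste(head(zero, 5), collapse = ", "),
           call. = FALSE)
    (X - mu) / s
  })
}

#' Multiplicative scatter correction
#'
#' Each row `x` is regressed on the reference spectrum (`x = a + b * ref`)
#' and replaced by `(x - a) / b`. The reference defaults to the column-wise
#' mean spectrum of the input and is returned as attribute `"reference"` so
#' it can be reused on test data.
#'
#' @param x a `spectra_block` or matrix.
#' @param reference optional reference spectrum (training fit).
#' @return object of the same kind; the corrected matrix carries
#'   `attr(, "reference")`.
#' @export
msc <- function(x, reference = NULL) {
  X <- get_X(x)
  ref <- reference %||% colMeans(X)
  assert_that(sd(ref) > 0, "reference spectrum must not be constant")
  rc <- ref - mean(ref)
  b <- as.numeric(X %*% rc) / sum(rc^2)
  if (any(b == 0))
    stop("zero MSC slope for row(s): ", paste(head(which(b == 0), 5), collapse = ", "),
         call. = FALSE)
  a <- rowMeans(X) - b * mean(ref)
  out <- (X - a) / b
  attr(out, "reference") <- ref
  if (inherits(x, "spectra_block")) {
    x$X <- out
    attr(x, "reference") <- ref
    x
  } else out
}

# least-squares polynomial filter coefficients for evaluation offset set
sg_coefs <- function(offsets, polyorder, deriv) {
  A <- outer(offsets, 0:polyorder, `^`)
  (solve(crossprod(A), t(A)))[deriv + 1L, ] * factorial(deriv)
}

# full n x n Savitzky-Golay operator matrix (row i of output = S[i,] %*% x)
sg_operator <- function(n, window, polyorder, deriv) {
  m <- (window - 1L) %/% 2L
  S <- matrix(0, n, n)
  core <- sg_coefs(-m:m, polyorder, deriv)
  for (i in (m + 1L):(n - m)) S[i, (i - m):(i + m)] <- core
  # edges: fit the polynomial on the first/last window, evaluate at offset
  for (i in seq_len(m)) {
    S[i, 1:window] <- sg_coefs(seq_len(window) - i, polyorder, deriv)
    j <- n - m + i
    S[j, (n - window + 1L):n] <- sg_coefs((n - window + 1L):n - j, polyorder, deriv)
  }
  S
}

#' Savitzky-Golay smoothing and differentiation
#'
#' Per-row local least-squares polynomial filtering. Derivatives are scaled
#' by the grid step so outputs are in absorbance per cm-1 (grid-invariant);
#' edge points use the polynomial fitted to the first/last full window.
#' Requires a (near-)uniform grid.
#'
#' @param x a `spectra_block` or matrix.
#' @param window odd window length, `window > polyorder`.
#' @param polyorder polynomial degree.
#' @param deriv derivative order (0, 1 or 2), `deriv <= polyorder`.
#' @param grid optional abscissa for plain matrices (defaults to unit
#'   spacing).
#' @return object of the same kind, same dimensions.
#' @export
savgol <- function(x, window = 9L, polyorder = 2L, deriv = 1L, grid = NULL) {
  assert_that(window %% 2L == 1L, "window must be odd")
  assert_that(window > polyorder, "window must exceed polyorder")
  assert_that(deriv %in% 0:2 && deriv <= polyorder, "deriv must be <= polyorder and in 0:2")
  g <- if (inherits(x, "spectra_block")) x$grid else grid %||% seq_len(ncol(get_X(x)))
  steps <- diff(g)
  h <- steps[1]
  assert_that(max(abs(steps - h)) <= 1e-6 * abs(h), "grid must be uniformly spaced")
  X <- get_X(x)
  assert_that(ncol(X) >= window, "window exceeds number of points")
  S <- sg_operator(ncol(X), as.integer(window), as.integer(polyorder), as.integer(deriv))
  out <- tcrossprod(X, S) / h^deriv
  if (inherits(x, "spectra_block")) {
    x$X <- out
    x
  } else out
}

#' Column-wise mean centering with reusable statistics
#'
#' @param X matrix.
#' @param center optional fitted column means (training statistics); when
#'   supplied they are used instead of recomputing from `X`.
#' @return centered matrix with attribute `"center"`.
#' @export
mean_center <- function(X, center = NULL) {
  X <- as.matrix(X)
  ctr <- center %||% colMeans(X)
  assert_that(length(ctr) == ncol(X), "center length must match ncol(X)")
  out <- sweep(X, 2, ctr)
  attr(out, "center") <- ctr
  out
}

#' Column-wise autoscaling with reusable statistics
#'
#' Centers each column and scales it to unit sample standard deviation.
#'
#' @param X matrix.
#' @param center,scale optional fitted statistics (training fit).
#' @return scaled matrix with attributes `"center"` and `"scale"`.
#' @export
autoscale <- function(X, center = NULL, scale = NULL) {
  X <- as.matrix(X)
  ctr <- center %||% colMeans(X)
  scl <- scale %||% col_sds(X)
  zero <- which(scl == 0)
  if (length(zero))
    stop("zero-variance column(s) cannot be autoscaled: ",
         paste(head(colnames(X)[zero] %||% zero, 5), collapse = ", "), call. = FALSE)
  out <- sweep(sweep(X, 2, ctr), 2, scl, `/`)
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}

#' Block scaling to unit total variance
#'
#' Multiplies each block by the reciprocal square root of its summed column
#' sample variance, so every block contributes total variance 1 while
#' within-block variance ratios are preserved.
#'
#' @param blocks list of matrices (equal row counts not required here).
#' @param factors optional previously fitted scale factors.
#' @return list of scaled matrices with attribute `"factors"`.
#' @export
block_scale <- function(blocks, factors = NULL) {
  tv <- vapply(blocks, function(B) sum(apply(as.matrix(B), 2, var)), 0)
  if (is.null(factors)) {
    if (any(tv == 0)) stop("zero-variance block cannot be block-scaled", call. = FALSE)
    factors <- 1 / sqrt(tv)
  }
  out <- Map(function(B, f) as.matrix(B) * f, blocks, factors)
  attr(out, "factors") <- factors
  out
}

#' Average the two replicate spectra of each fruit
#'
#' @param block a [spectra_block()] with 1 or 2 replicate rows per fruit.
#' @return `spectra_block` with one row per fruit (first-seen fruit order).
#' @export
average_replicates <- function(block) {
  tab <- table(block$sample_id)
  if (any(tab > 2)) stop("more than two replicates for fruit(s): ",
                         paste(head(names(tab)[tab > 2], 5), collapse = ", "),
                         call. = FALSE)
  ids <- unique(block$sample_id)
  first <- match(ids, block$sample_id)
  X <- rowsum(block$X, group = factor(block$sample_id, levels = ids)) /
    as.integer(tab[ids])
  spectra_block(X, block$grid, sample_id = ids,
                cultivar = block$cultivar[first],
                replicate = rep(1L, length(ids)))
}

#' Build a preprocessing chain specification
#'
#' `steps` is an ordered list of `list(name = ..., <parameters>)` entries;
#' recognized names: `trim`, `snv`, `msc`, `savgol`, `mean_center`,
#' `autoscale`. Fit the chain on training data with [fit_preprocess()],
#' then transform new data with [apply_preprocess()].
#'
#' @param steps list of step descriptors.
#' @return object of class `preprocess_spec`.
#' @export
preprocess_spec <- function(steps) {
  ok <- c("trim", "snv", "msc", "savgol", "mean_center", "autoscale")
  for (s in steps) assert_that(s$name %in% ok,
                               paste("unknown preprocessing step:", s$name))
  structure(list(steps = steps), class = "preprocess_spec")
}

#' Default NIR preprocessing chain
#'
#' Trim to 9000-4000 cm-1, first Savitzky-Golay derivative (window 9,
#' second-order polynomial), then mean centering — the treatment tagged
#' "9der1" in the classification experiments.
#'
#' @return a [preprocess_spec()].
#' @export
default_nir_preprocess <- function() {
  preprocess_spec(list(list(name = "trim", low = 4000, high = 9000),
                       list(name = "savgol", window = 9L, polyorder = 2L, deriv = 1L),
                       list(name = "mean_center")))
}

run_pp_step <- function(step, x, fitted = NULL) {
  switch(step$name,
    trim = list(x = trim_range(x, low = step$low, high = step$high), fit = NULL),
    snv = list(x = snv(x), fit = NULL),
    msc = {
      out <- msc(x, reference = fitted$reference)
      list(x = out, fit = list(reference = attr(out, "reference")))
    },
    savgol = list(x = savgol(x, window = step$window %||% 9L,
                             polyorder = step$polyorder %||% 2L,
                             deriv = step$deriv %||% 1L), fit = NULL),
    mean_center = {
      out <- with_block(x, function(X) mean_center(X, center = fitted$center))
      list(x = out, fit = list(center = attr(get_X(out), "center")))
    },
    autoscale = {
      out <- with_block(x, function(X)
        autoscale(X, center = fitted$center, scale = fitted$scale))
      list(x = out,
           fit = list(center = attr(get_X(out), "center"),
                      scale = attr(get_X(out), "scale")))
    })
}

#' Fit a preprocessing chain on training data
#'
#' @param spec a [preprocess_spec()].
#' @param x training `spectra_block` or matrix.
#' @return list with `x` (the transformed training data) and `fitted` (a
#'   `fitted_preprocess` object for [apply_preprocess()]).
#' @export
fit_preprocess <- function(spec, x) {
  fits <- vector("list", length(spec$steps))
  for (i in seq_along(spec$steps)) {
    r <- run_pp_step(spec$steps[[i]], x)
    x <- r$x
    fits[[i]] <- r$fit
  }
  list(x = x, fitted = structure(list(spec = spec, fits = fits),
                                 class = "fitted_preprocess"))
}

#' Apply a fitted preprocessing chain to new data
#'
#' Column statistics (MSC reference, centers, scales) stored at fit time
#' are reused; nothing is recomputed from the new data.
#'
#' @param fitted a `fitted_preprocess` from [fit_preprocess()].
#' @param x new `spectra_block` or matrix with matching variables.
#' @return transformed data.
#' @export
apply_preprocess <- function(fitted, x) {
  assert_that(inherits(fitted, "fitted_preprocess"), "fitted_preprocess required")
  for (i in seq_along(fitted$spec$steps)) {
    st <- fitted$spec$steps[[i]]
    if (st$name %in% c("msc", "mean_center", "autoscale"))
      assert_that(!is.null(fitted$fits[[i]]), "chain must be fitted before applying")
    x <- run_pp_step(st, x, fitted = fitted$fits[[i]])$x
  }
  x
}
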