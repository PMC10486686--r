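# Deterministic sample-set partitioning and cross-validation planning.

#' Duplex train/test partitioning
#'
#' Classic duplex on Euclidean distance: the two most mutually distant
#' points are assigned to the training set, the two most distant remaining
#' points to the test set, and the sets alternate taking the most distant
#' remaining pair until the test set holds `n_test` samples; the remainder
#' goes to training. Fully deterministic; distance ties are broken by
#' lowest row index, and a final single test slot takes the lower-index
#' member of the selected pair.
#'
#' @param X data matrix (rows = samples); distances are computed on
#'   autoscaled columns unless `autoscale = FALSE` (use `FALSE` for
#'   already-pretreated spectra).
#' @param n_test number of test samples, `0 <= n_test <= nrow(X) - 2`.
#' @param autoscale autoscale columns before computing distances.
#' @return object of class `split_assignment`: integer vectors `train` and
#'   `test` (disjoint, union = all rows).
#' @export
duplex_split <- function(X, n_test, autoscale = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  assert_that(n_test >= 0 && n_test <= n - 2L,
              sprintf("n_test must be in [0, %d]", n - 2L))
  if (autoscale) {
    s <- col_sds(X)
    keep <- s > 0
    X <- sweep(sweep(X[, keep, drop = FALSE], 2, colMeans(X[, keep, drop = FALSE])),
               2, s[keep], `/`)
  }
  if (n_test == 0L)
    return(structure(list(train = seq_len(n), test = integer(0)),
                     class = "split_assignment"))
  D <- as.matrix(dist(X))
  remaining <- rep(TRUE, n)
  train <- integer(0); test <- integer(0)
  target <- "train"
  most_distant_pair <- function() {
    idx <- which(remaining)
    Dr <- D[idx, idx, drop = FALSE]
    Dr[lower.tri(Dr, diag = TRUE)] <- -Inf
    best <- which(Dr == max(Dr), arr.ind = TRUE)
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]  # lowest indices
    c(idx[best[1]], idx[best[2]])
  }
  while (sum(remaining) > 0L) {
    if (length(test) >= n_test) {       # test quota met: rest to training
      train <- c(train, which(remaining))
      break
    }
    if (sum(remaining) == 1L) {
      if (target == "test") test <- c(test, which(remaining))
      else train <- c(train, which(remaining))
      break
    }
    pair <- most_distant_pair()
    if (target == "train") {
      train <- c(train, pair)
      remaining[pair] <- FALSE
      target <- "test"
    } else {
      take <- if (n_test - length(test) == 1L) pair[1] else pair
      test <- c(test, take)
      remaining[take] <- FALSE
      target <- "train"
    }
  }
  structure(list(train = sort(train), test = sort(test)),
            class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  cat(sprintf("<split_assignment> %d train / %d test\n",
              length(x$train), length(x$test)))
  invisible(x)
}

#' Venetian-blinds cross-validation fold plan
#'
#' Sample at position `i` (1-based dataset order) goes to fold
#' `(i - 1) %% segments + 1`; folds interleave through the dataset and
#' their sizes differ by at most one. Assignment depends only on indices,
#' never on feature values.
#'
#' @param n number of samples.
#' @param segments number of folds, `2 <= segments <= n`.
#' @return integer fold index per sample.
#' @export
venetian_blinds <- function(n, segments = 5L) {
  assert_that(segments >= 2L, "segments must be >= 2")
  assert_that(segments <= n, "segments must not exceed n")
  (seq_len(n) - 1L) %% as.integer(segments) + 1L
}

#' Select the number of latent variables by the one-standard-error rule
#'
#' Returns the smallest candidate whose cross-validated error is within
#' one standard error of the minimum (parsimony rule). With zero standard
#' errors this is the first minimum.
#'
#' @param cv_errors numeric vector of CV errors, one per candidate count
#'   (candidate k = position k).
#' @param cv_se optional standard errors of the same length (default 0).
#' @return the selected candidate index.
#' @export
select_lvs <- function(cv_errors, cv_se = NULL) {
  assert_that(length(cv_errors) >= 1, "cv_errors must be non-empty")
  cv_se <- cv_se %||% rep(0, length(cv_errors))
  assert_that(length(cv_se) == length(cv_errors),
              "cv_se must match cv_errors in length")
  best <- which.min(cv_errors)
  which(cv_errors <= cv_errors[best] + cv_se[best])[1]
}
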