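# Principal component analysis via SVD of the (optionally centered/scaled)
# data matrix; equivalent to eigendecomposition of the sample covariance.

#' Fit a principal component analysis model
#'
#' Components are ordered by decreasing eigenvalue (sample variance along
#' the component, denominator n-1). A deterministic sign convention is
#' applied: within each loading vector, the element of largest magnitude
#' (lowest index on ties) is made positive, so repeated fits are
#' bit-identical.
#'
#' @param X matrix (observations x variables), already pretreated upstream.
#' @param n_components number of components to retain
#'   (`<= min(nrow - 1, ncol)`).
#' @param center,scale whether to center / autoscale columns before
#'   decomposition (defaults: center only).
#' @return object of class `pca_model`: `center`, `scale`, `P` (loadings,
#'   variables x components, orthonormal), `T` (scores), `eigenvalues`,
#'   `explained` (fraction of total variance), `total_variance`.
#' @export
fit_pca <- function(X, n_components, center = TRUE, scale = FALSE) {
  X <- as.matrix(X)
  kmax <- min(nrow(X) - 1L, ncol(X))
  assert_that(n_components >= 1 && n_components <= kmax,
              sprintf("n_components must be in [1, %d]", kmax))
  ctr <- if (center) colMeans(X) else rep(0, ncol(X))
  scl <- if (scale) col_sds(X) else rep(1, ncol(X))
  if (any(scl == 0)) stop("zero-variance column; cannot scale", call. = FALSE)
  Xp <- sweep(sweep(X, 2, ctr), 2, scl, `/`)
  sv <- svd(Xp, nu = 0, nv = kmax)
  P <- sv$v[, seq_len(n_components), drop = FALSE]
  for (k in seq_len(ncol(P))) {
    j <- which.max(abs(P[, k]))
    if (P[j, k] < 0) P[, k] <- -P[, k]
  }
  eig <- sv$d[seq_len(kmax)]^2 / (nrow(X) - 1L)
  total <- sum(apply(Xp, 2, var))
  structure(list(center = ctr, scale = scl, P = P,
                 T = Xp %*% P,
                 eigenvalues = eig[seq_len(n_components)],
                 explained = eig[seq_len(n_components)] / total,
                 all_eigenvalues = eig,
                 total_variance = total,
                 n_components = n_components),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d components, explained: %s\n", x$n_components,
              paste(sprintf("%.1f%%", 100 * x$explained), collapse = " ")))
  invisible(x)
}

#' Project new observations onto a fitted PCA model
#'
#' Uses the model's stored centering/scaling statistics; never refits.
#'
#' @param model a `pca_model`.
#' @param X_new matrix with the same variables as the training data.
#' @return score matrix (observations x components).
#' @export
project <- function(model, X_new) {
  X_new <- as.matrix(X_new)
  assert_that(ncol(X_new) == length(model$center),
              sprintf("X_new has %d columns, model expects %d",
                      ncol(X_new), length(model$center)))
  sweep(sweep(X_new, 2, model$center), 2, model$scale, `/`) %*% model$P
}

#' Per-group confidence-ellipse summary of a score plane
#'
#' For each group, the ellipse center is the mean score on each of the two
#' chosen axes and the radius is the sample standard deviation along each
#' axis (axis-aligned, 1-sd ellipses).
#'
#' @param scores score matrix.
#' @param labels group label per row (>= 2 observations per group).
#' @param axes integer pair of component indices (default `c(1, 2)`).
#' @return data.frame with `group`, `center_x`, `center_y`, `radius_x`,
#'   `radius_y`.
#' @export
ellipse_summary <- function(scores, labels, axes = c(1, 2)) {
  scores <- as.matrix(scores)
  assert_that(length(axes) == 2 && all(axes <= ncol(scores)),
              "axes must index two score columns")
  tab <- table(labels)
  if (any(tab < 2)) stop("singleton group(s): ",
                         paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)
  groups <- names(tab)
  out <- do.call(rbind, lapply(groups, function(g) {
    S <- scores[labels == g, axes, drop = FALSE]
    data.frame(group = g, center_x = mean(S[, 1]), center_y = mean(S[, 2]),
               radius_x = sd(S[, 1]), radius_y = sd(S[, 2]))
  }))
  rownames(out) <- NULL
  out
}
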