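# Partial least squares discriminant analysis. The PLS core is an
# iterative-deflation (NIPALS) implementation for a single dummy response
# (PLS1) or a dummy matrix (PLS2), returning the cumulative regression
# coefficients after each latent variable so cross-validation over a grid
# of dimensionalities needs only one fit per fold.

pls_core <- function(X, Y, n_lv, tol = 1e-10, max_iter = 500L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); m <- ncol(Y)
  assert_that(nrow(Y) == n, "X and Y row counts differ")
  assert_that(n_lv >= 1, "n_lv must be >= 1")
  cx <- colMeans(X); cy <- colMeans(Y)
  Xd <- sweep(X, 2, cx); Yd <- sweep(Y, 2, cy)
  W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv); Q <- matrix(0, m, n_lv)
  A <- 0L
  for (a in seq_len(n_lv)) {
    if (m == 1L) {
      w <- crossprod(Xd, Yd)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-14) break
      w <- w / nw
      tt <- Xd %*% w
    } else {
      u <- Yd[, which.max(apply(Yd, 2, var)), drop = FALSE]
      tt <- NULL
      for (it in seq_len(max_iter)) {
        w <- crossprod(Xd, u)
        nw <- sqrt(sum(w^2))
        if (nw < 1e-14) break
        w <- w / nw
        t_new <- Xd %*% w
        q <- crossprod(Yd, t_new) / sum(t_new^2)
        u <- Yd %*% q / sum(q^2)
        if (!is.null(tt) && sqrt(sum((t_new - tt)^2)) < tol * sqrt(sum(t_new^2))) {
          tt <- t_new; break
        }
        tt <- t_new
      }
      if (is.null(tt) || sqrt(sum(w^2)) < 1e-14) break
    }
    ss <- sum(tt^2)
    if (ss < 1e-14) break
    pl <- crossprod(Xd, tt) / ss
    q <- crossprod(Yd, tt) / ss
    Xd <- Xd - tcrossprod(tt, pl)
    Yd <- Yd - tcrossprod(tt, q)
    W[, a] <- w; P[, a] <- pl; Q[, a] <- q
    A <- a
  }
  if (A == 0L) stop("no PLS component could be extracted (rank-deficient X or constant Y)",
                    call. = FALSE)
  W <- W[, seq_len(A), drop = FALSE]
  P <- P[, seq_len(A), drop = FALSE]
  Q <- Q[, seq_len(A), drop = FALSE]
  # cumulative coefficients B_a = W_a (P_a' W_a)^-1 Q_a' for a = 1..A
  B <- array(0, dim = c(p, m, A))
  for (a in seq_len(A)) {
    Wa <- W[, seq_len(a), drop = FALSE]
    Pa <- P[, seq_len(a), drop = FALSE]
    Qa <- Q[, seq_len(a), drop = FALSE]
    B[, , a] <- Wa %*% solve(crossprod(Pa, Wa), t(Qa))
  }
  list(W = W, P = P, Q = Q, B = B, center_x = cx, center_y = cy, n_lv = A)
}

#' Specification of a binary classification mode
#'
#' @param id mode label.
#' @param positive,negative disjoint, non-empty cultivar sets coding the
#'   1 (belonging) and 0 (not belonging) classes.
#' @return object of class `mode_spec`.
#' @export
mode_spec <- function(id, positive, negative) {
  assert_that(length(positive) >= 1 && length(negative) >= 1,
              "both class sets must be non-empty")
  assert_that(length(intersect(positive, negative)) == 0,
              "class sets must be disjoint")
  structure(list(id = id, positive = positive, negative = negative),
            class = "mode_spec")
}

#' The standard classification modes for the four reference cultivars
#'
#' MODE 1 discriminates the Romina+Sibilla pair from Silvia+Cristina;
#' MODE 2 singles out Silvia and MODE 3 Cristina. For MODE 2/3 the
#' positive (1-coded) class is the larger three-cultivar group. `multi`
#' denotes the simultaneous four-class model.
#'
#' @return named list of `mode_spec` objects (plus the `"multi"` marker).
#' @export
plsda_modes <- function() {
  all4 <- c("Romina", "Sibilla", "Silvia", "Cristina")
  list(
    mode1 = mode_spec("MODE1", positive = c("Romina", "Sibilla"),
                      negative = c("Silvia", "Cristina")),
    mode2 = mode_spec("MODE2", positive = setdiff(all4, "Silvia"),
                      negative = "Silvia"),
    mode3 = mode_spec("MODE3", positive = setdiff(all4, "Cristina"),
                      negative = "Cristina"),
    multi = structure(list(id = "MULTI", classes = all4),
                      class = c("mode_spec_multi", "mode_spec")))
}

#' Fit a two-class PLS-DA model
#'
#' The class membership is dummy-coded 1 (positive set) / 0 (negative
#' set) and regressed on mean-centered `X` by NIPALS PLS1.
#'
#' @param X feature matrix.
#' @param labels cultivar label per row.
#' @param mode a [mode_spec()]; rows outside both class sets are rejected.
#' @param n_lv number of latent variables (`>= 1`, at most the rank of
#'   centered `X`).
#' @param threshold decision threshold on predicted y (default 0.5; usually
#'   replaced by [choose_threshold()] on CV predictions).
#' @return object of class `plsda_model`.
#' @export
fit_plsda <- function(X, labels, mode, n_lv, threshold = 0.5) {
  known <- labels %in% c(mode$positive, mode$negative)
  assert_that(all(known), "labels outside the mode's class sets")
  y <- as.numeric(labels %in% mode$positive)
  if (length(unique(y)) < 2L)
    stop("both classes must be present in the training data", call. = FALSE)
  kmax <- min(nrow(as.matrix(X)) - 1L, ncol(as.matrix(X)))
  assert_that(n_lv <= kmax, sprintf("n_lv must be <= %d", kmax))
  core <- pls_core(X, matrix(y), n_lv)
  structure(c(core, list(mode = mode, threshold = threshold,
                         fitted = drop(sweep(as.matrix(X), 2, core$center_x) %*%
                                         core$B[, 1, core$n_lv]) + core$center_y)),
            class = "plsda_model")
}

#' Predict continuous class scores from a PLS-DA model
#'
#' @param model a `plsda_model` (or multiclass `plsda_multi`).
#' @param X_new feature matrix with matching columns.
#' @param n_lv optionally predict with fewer latent variables than fitted.
#' @return numeric vector of predicted y (matrix for multiclass).
#' @export
predict_scores <- function(model, X_new, n_lv = NULL) {
  X_new <- as.matrix(X_new)
  assert_that(ncol(X_new) == length(model$center_x),
              sprintf("X_new has %d columns, model expects %d",
                      ncol(X_new), length(model$center_x)))
  a <- n_lv %||% model$n_lv
  assert_that(a >= 1 && a <= model$n_lv, "n_lv out of fitted range")
  Yh <- sweep(X_new, 2, model$center_x) %*% model$B[, , a] +
    matrix(model$center_y, nrow(X_new), length(model$center_y), byrow = TRUE)
  if (ncol(Yh) == 1L) drop(Yh) else Yh
}

#' ROC curve and area under the curve
#'
#' Thresholds sweep the distinct score values (ties grouped); the curve is
#' the (FPR, TPR) polyline and the AUC its trapezoidal area.
#'
#' @param y_true 0/1 vector (both classes present).
#' @param y_score continuous classifier scores, higher = more positive.
#' @return list with `curve` (data.frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_curve <- function(y_true, y_score) {
  assert_that(length(y_true) == length(y_score), "length mismatch")
  y_true <- as.integer(y_true)
  assert_that(all(y_true %in% 0:1), "y_true must be 0/1")
  np <- sum(y_true == 1L); nn <- sum(y_true == 0L)
  if (np == 0L || nn == 0L) stop("both classes must be present", call. = FALSE)
  o <- order(y_score, decreasing = TRUE)
  ys <- y_score[o]; yt <- y_true[o]
  grp <- cumsum(c(TRUE, diff(ys) != 0))        # groups of tied scores
  tp <- cumsum(yt); fp <- cumsum(1L - yt)
  last <- which(!duplicated(grp, fromLast = TRUE))
  curve <- data.frame(threshold = ys[last], fpr = fp[last] / nn, tpr = tp[last] / np)
  curve <- rbind(data.frame(threshold = Inf, fpr = 0, tpr = 0), curve)
  auc <- sum(diff(curve$fpr) * (head(curve$tpr, -1) + tail(curve$tpr, -1)) / 2)
  list(curve = curve, auc = auc)
}

#' Choose the decision threshold minimizing CV misclassification error
#'
#' Candidate thresholds are the midpoints between consecutive distinct
#' score values (plus one below and one above the range); among candidates
#' achieving the minimal error, the midpoint of the tied range is
#' returned.
#'
#' @param cv_y_true 0/1 vector of cross-validated truths.
#' @param cv_y_score cross-validated continuous predictions.
#' @return numeric threshold (predict class 1 when score >= threshold).
#' @export
choose_threshold <- function(cv_y_true, cv_y_score) {
  y <- as.integer(cv_y_true)
  if (length(unique(y)) < 2L) stop("both classes must be present", call. = FALSE)
  u <- sort(unique(cv_y_score))
  cand <- c(u[1] - 1, (head(u, -1) + tail(u, -1)) / 2, u[length(u)] + 1)
  err <- vapply(cand, function(th) mean((cv_y_score >= th) != (y == 1L)), 0)
  best <- which(err == min(err))
  # optimal candidates can form several disjoint runs; take the longest
  # contiguous run (first on ties) and return its midpoint
  runs <- split(best, cumsum(c(1L, diff(best) != 1L)))
  run <- runs[[which.max(lengths(runs))]]
  mean(range(cand[run]))
}

#' Binary classification performance report
#'
#' @param y_true 0/1 truth vector.
#' @param y_pred_class 0/1 predicted classes (same length).
#' @return list with confusion counts and percentage rates: `tpr`
#'   (sensitivity), `tnr` (specificity), `fpr` (= 100 - TNR), `error`
#'   (overall misclassification %).
#' @export
evaluate <- function(y_true, y_pred_class) {
  assert_that(length(y_true) == length(y_pred_class), "length mismatch")
  y <- as.integer(y_true); yh <- as.integer(y_pred_class)
  assert_that(all(y %in% 0:1) && all(yh %in% 0:1), "labels must be binary 0/1")
  tp <- sum(y == 1L & yh == 1L); fn <- sum(y == 1L & yh == 0L)
  tn <- sum(y == 0L & yh == 0L); fp <- sum(y == 0L & yh == 1L)
  list(tp = tp, fn = fn, tn = tn, fp = fp,
       tpr = 100 * tp / (tp + fn),
       tnr = 100 * tn / (tn + fp),
       fpr = 100 * fp / (tn + fp),
       error = 100 * (fp + fn) / length(y))
}

#' Fit a multiclass PLS-DA model
#'
#' PLS2 regression of the class-indicator dummy matrix on mean-centered
#' `X`; the predicted class is the argmax of the predicted dummy columns.
#'
#' @param X feature matrix.
#' @param labels class label per row (>= 2 classes).
#' @param n_lv number of latent variables.
#' @return object of class `plsda_multi` with the PLS2 core and `classes`.
#' @export
fit_multiclass <- function(X, labels, n_lv) {
  classes <- sort(unique(as.character(labels)))
  assert_that(length(classes) >= 2, "need at least two classes")
  Y <- outer(as.character(labels), classes, `==`) * 1
  colnames(Y) <- classes
  core <- pls_core(X, Y, n_lv)
  structure(c(core, list(classes = classes)), class = "plsda_multi")
}

#' Predict classes from a multiclass PLS-DA model
#'
#' @param model a `plsda_multi`.
#' @param X_new feature matrix.
#' @return character vector of predicted class labels.
#' @export
predict_multiclass <- function(model, X_new) {
  Yh <- predict_scores(model, X_new)
  model$classes[max.col(Yh, ties.method = "first")]
}
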