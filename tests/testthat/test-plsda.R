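make_mode <- function() mode_spec("AB", positive = "A", negative = "B")

test_that("PLS core matches hand NIPALS and OLS at full rank", {
  # first weight vector is proportional to X'y on centered data
  X <- matrix(c(1, 2, 3, 4,
                0, 1, 0, 1,
                2, 2, 1, 1), 4, 3)
  y <- c(0, 0, 1, 1)
  core <- strawnir:::pls_core(X, matrix(y), 1)
  Xc <- sweep(X, 2, colMeans(X)); yc <- y - mean(y)
  w_hand <- crossprod(Xc, yc)
  w_hand <- w_hand / sqrt(sum(w_hand^2))
  expect_equal(unname(core$W[, 1]), unname(drop(w_hand)), tolerance = 1e-10)

  # full-rank PLS equals ordinary least squares
  set.seed(40)
  X2 <- matrix(rnorm(100), 20, 5)
  y2 <- rnorm(20)
  core2 <- strawnir:::pls_core(X2, matrix(y2), 5)
  pred <- sweep(X2, 2, core2$center_x) %*% core2$B[, 1, 5] + core2$center_y
  ols <- unname(fitted(lm(y2 ~ X2)))
  expect_equal(unname(drop(pred)), ols, tolerance = 1e-8)

  # telescoping: a k-LV fit extends the (k-1)-LV fit
  core3 <- strawnir:::pls_core(X2, matrix(y2), 3)
  expect_equal(core3$W[, 1:2], core2$W[, 1:2], tolerance = 1e-12)
  expect_equal(core3$B[, , 2], core2$B[, , 2], tolerance = 1e-12)
})

test_that("fit_plsda fits the dummy response and predicts deterministically", {
  set.seed(41)
  z <- c(rnorm(10, -2), rnorm(10, 2))
  X <- cbind(z, matrix(rnorm(40, sd = 0.1), 20, 2))
  labels <- rep(c("B", "A"), each = 10)
  y <- as.numeric(labels == "A")
  m <- fit_plsda(X, labels, make_mode(), n_lv = 1)
  # y exactly linear in one column -> near-zero training residual
  X3 <- cbind(y * 2 + 1, matrix(0, 20, 1))
  m3 <- fit_plsda(X3 + matrix(rnorm(40, sd = 1e-8), 20), labels, make_mode(), 1)
  expect_lt(max(abs(m3$fitted - y)), 1e-5)

  expect_equal(unname(predict_scores(m, X)), unname(m$fitted), tolerance = 1e-12)
  ctr <- matrix(m$center_x, 1)
  expect_equal(unname(predict_scores(m, ctr)), mean(y), tolerance = 1e-12)
  Xdup <- X[c(3, 3), ]
  p <- predict_scores(m, Xdup)
  expect_identical(p[1], p[2])

  expect_error(fit_plsda(X, rep("A", 20), make_mode(), 1), "both classes")
  expect_error(fit_plsda(X, labels, make_mode(), n_lv = 25), "n_lv")

  # shifting test spectra leaves stored statistics untouched; prediction
  # changes only through the trained coefficients acting on the shift
  shift <- 0.7
  p0 <- predict_scores(m, X)
  p1 <- predict_scores(m, X + shift)
  expect_equal(unname(p1 - p0), rep(shift * sum(m$B[, 1, m$n_lv]), 20),
               tolerance = 1e-10)
})

test_that("ROC curve agrees with the pair-counting oracle", {
  y <- c(1, 1, 1, 0, 0, 1, 0, 0)
  s <- c(0.9, 0.8, 0.35, 0.4, 0.3, 0.6, 0.6, 0.1)
  r <- roc_curve(y, s)
  pos <- s[y == 1]; neg <- s[y == 0]
  pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(r$auc, mean(pairs), tolerance = 1e-12)

  expect_equal(roc_curve(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))$auc, 1)
  expect_equal(roc_curve(c(0, 0, 1, 1), 1 - c(0.1, 0.2, 0.8, 0.9))$auc, 0)
  # invariance under strictly monotone transforms
  expect_equal(roc_curve(y, exp(3 * s))$auc, r$auc, tolerance = 1e-12)
  expect_error(roc_curve(rep(1, 4), runif(4)), "both classes")
})

test_that("threshold choice minimizes CV error, ties to the midpoint", {
  y <- c(0, 0, 0, 1, 1, 1)
  s <- c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9)
  expect_equal(choose_threshold(y, s), 0.5)

  set.seed(42)
  yr <- rbinom(40, 1, 0.5)
  sr <- runif(40)
  th <- choose_threshold(yr, sr)
  err <- function(t) mean((sr >= t) != (yr == 1))
  # exhaustive scan over a fine grid cannot beat the chosen threshold
  grid <- seq(-0.1, 1.1, by = 1e-3)
  expect_lte(err(th), min(vapply(grid, err, 0)) + 1e-12)

  set.seed(43)
  sg <- c(rnorm(2000, 0), rnorm(2000, 4))
  yg <- rep(0:1, each = 2000)
  expect_lt(abs(choose_threshold(yg, sg) - 2), 0.35)
})

test_that("evaluation reports the standard confusion rates", {
  ev <- evaluate(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(ev[c("tpr", "tnr", "error")], list(tpr = 100, tnr = 100, error = 0))
  yt <- c(rep(1, 10), rep(0, 10))
  yp <- c(rep(1, 9), 0, rep(0, 8), 1, 1)
  ev2 <- evaluate(yt, yp)
  expect_equal(ev2$tpr, 90)
  expect_equal(ev2$tnr, 80)
  expect_equal(ev2$error, 15)
  expect_equal(ev2$fpr, 100 - ev2$tnr)

  set.seed(44)
  for (i in 1:20) {
    a <- rbinom(30, 1, 0.5); b <- rbinom(30, 1, 0.5)
    if (length(unique(a)) < 2) next
    ev3 <- evaluate(a, b)
    expect_equal(ev3$error, 100 * mean(a != b))
    expect_equal(ev3$tp + ev3$fn + ev3$tn + ev3$fp, 30)
  }
})

test_that("multiclass PLS-DA recovers well-separated classes", {
  set.seed(45)
  centers <- matrix(c(0, 0, 6, 0, 0, 6, 6, 6), 4, 2, byrow = TRUE)
  X <- centers[rep(1:4, each = 25), ] + matrix(rnorm(200, sd = 0.4), 100, 2)
  X <- cbind(X, matrix(rnorm(300, sd = 0.2), 100, 3))
  labels <- rep(c("c1", "c2", "c3", "c4"), each = 25)
  m <- fit_multiclass(X, labels, n_lv = 4)
  pred <- predict_multiclass(m, X)
  for (cl in unique(labels))
    expect_gt(mean(pred[labels == cl] == cl), 0.95)

  # two-class agreement with the binary model on separable data
  sub <- labels %in% c("c1", "c3")
  mb <- fit_plsda(X[sub, ], labels[sub],
                  mode_spec("x", positive = "c3", negative = "c1"),
                  n_lv = 2, threshold = 0.5)
  m2 <- fit_multiclass(X[sub, ], labels[sub], n_lv = 2)
  pb <- ifelse(predict_scores(mb, X[sub, ]) >= 0.5, "c3", "c1")
  expect_equal(predict_multiclass(m2, X[sub, ]), pb)

  # one observation per class at full rank memorizes the training set
  X1 <- diag(4) + 0.1
  lab1 <- paste0("k", 1:4)
  m1 <- fit_multiclass(X1, lab1, n_lv = 3)
  expect_equal(predict_multiclass(m1, X1), lab1)
})
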