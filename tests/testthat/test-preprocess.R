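test_that("trim_range matches a linear-scan oracle and handles edge cases", {
  panel <- generate_lab_panel(n_per_cultivar = 2, seed = 1)
  sp <- generate_spectra(panel, seed = 1)
  tr <- trim_range(sp, 4000, 9000)
  oracle <- sum(sp$grid >= 4000 & sp$grid <= 9000)
  expect_equal(ncol(tr$X), oracle)
  expect_equal(oracle, 1297L)           # closed-interval count on the default grid
  expect_true(all(tr$grid >= 4000 & tr$grid <= 9000))
  expect_equal(nrow(tr$X), nrow(sp$X))

  full <- trim_range(sp, min(sp$grid), max(sp$grid))
  expect_equal(full$X, sp$X)
  expect_error(trim_range(sp, 11000, 12000), "no grid points")
})

test_that("SNV standardizes rows and is idempotent", {
  b <- toy_block(n = 1, p = 3)
  b$X[1, ] <- c(1, 2, 3)
  expect_equal(unname(snv(b)$X[1, ]), c(-1, 0, 1))

  set.seed(1)
  X <- matrix(rnorm(50 * 20, 2, 3), 50)
  Z <- snv(X)
  expect_lt(max(abs(rowMeans(Z))), 1e-12)
  expect_lt(max(abs(apply(Z, 1, sd) - 1)), 1e-12)
  expect_equal(snv(Z), Z, tolerance = 1e-12)

  Xc <- X; Xc[3, ] <- 5
  expect_error(snv(Xc), "constant row")
})

test_that("MSC inverts affine scatter against the reference", {
  set.seed(2)
  ref <- sin(seq(0, 3, length.out = 30)) + 2
  X <- rbind(ref, 2 * ref + 3, ref + rnorm(30, sd = 0.05))
  # row equal to the reference is returned unchanged (a = 0, b = 1)
  out2 <- msc(matrix(ref, 1), reference = ref)
  expect_equal(unname(out2[1, ]), unname(ref), tolerance = 1e-12)
  out3 <- msc(matrix(2 * ref + 3, 1), reference = ref)
  expect_equal(unname(out3[1, ]), unname(ref), tolerance = 1e-12)
  # refit oracle: corrected rows regress on the fitted reference with (0, 1)
  out <- msc(X)
  used_ref <- attr(out, "reference")
  for (i in seq_len(nrow(out))) {
    fit <- lm(out[i, ] ~ used_ref)
    expect_lt(abs(coef(fit)[1]), 1e-10)
    expect_lt(abs(coef(fit)[2] - 1), 1e-10)
  }
  # the stored reference is reused on new data, not recomputed
  corrected <- msc(rbind(3 * used_ref - 1), reference = used_ref)
  expect_equal(unname(corrected[1, ]), unname(used_ref), tolerance = 1e-10)
})

test_that("Savitzky-Golay derivative is exact on polynomials", {
  i <- 1:40
  X <- rbind(i^2)
  d1 <- savgol(X, window = 9, polyorder = 2, deriv = 1)
  interior <- 5:36
  expect_equal(unname(d1[1, interior]), 2 * i[interior], tolerance = 1e-9)
  # edges come from the fitted quadratic, exact here too
  expect_equal(unname(d1[1, ]), 2 * i, tolerance = 1e-9)

  expect_equal(unname(savgol(rbind(rep(7, 20)), 9, 2, 1)[1, ]), rep(0, 20),
               tolerance = 1e-12)
  sm <- savgol(X, window = 9, polyorder = 2, deriv = 0)
  expect_equal(unname(sm[1, ]), unname(X[1, ]), tolerance = 1e-8)

  # derivative is reported per unit of the grid, not per index
  g <- seq(100, 2, length.out = 50)          # descending, step -2
  b <- toy_block(n = 1, p = 50)
  b$grid <- g
  b$X[1, ] <- 3 * g
  expect_equal(unname(savgol(b, 9, 2, 1)$X[1, ]), rep(3, 50), tolerance = 1e-9)

  expect_error(savgol(X, window = 8), "odd")
  expect_error(savgol(X, window = 3, polyorder = 3), "exceed")
  expect_error(savgol(rbind(rnorm(10)), grid = c(1, 2, 4, seq(5, 11)), window = 5),
               "uniform")
})

test_that("centering and autoscaling reuse fitted statistics", {
  X <- cbind(a = c(2, 4, 6), b = c(1, 1, 4))
  expect_equal(unname(mean_center(X)[, 1]), c(-2, 0, 2))

  set.seed(3)
  M <- matrix(rnorm(40, 5, 2), 10)
  A <- autoscale(M)
  expect_lt(max(abs(colMeans(A))), 1e-12)
  expect_lt(max(abs(apply(A, 2, sd) - 1)), 1e-12)

  # training statistics applied to a shifted test set: the stored means are
  # used, so the shift survives
  shifted <- M + 10
  A2 <- autoscale(shifted, center = attr(A, "center"), scale = attr(A, "scale"))
  expect_equal(colMeans(A2), 10 / attr(A, "scale"), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(mean_center(M, center = colMeans(M)), mean_center(M),
               tolerance = 1e-14, ignore_attr = TRUE)

  Z <- M; Z[, 2] <- 3
  expect_error(autoscale(Z), "zero-variance")
})

test_that("block scaling equalizes total variance, preserving ratios", {
  set.seed(4)
  B1 <- matrix(rnorm(30, sd = 3), 10)
  B2 <- matrix(rnorm(10 * 50, sd = 0.1), 10)
  out <- block_scale(list(B1, B2))
  for (B in out) expect_equal(sum(apply(B, 2, var)), 1, tolerance = 1e-12)
  r_before <- var(B1[, 1]) / var(B1[, 2])
  r_after <- var(out[[1]][, 1]) / var(out[[1]][, 2])
  expect_equal(r_after, r_before, tolerance = 1e-12)

  B4 <- matrix(c(1, -1, 1, -1, 3, -3, 3, -3), 4)   # column variances sum to 4
  sc <- block_scale(list(B4))
  expect_equal(attr(sc, "factors")[[1]], 1 / sqrt(sum(apply(B4, 2, var))))
  expect_error(block_scale(list(matrix(1, 3, 2))), "zero-variance")
})

test_that("replicate averaging collapses fruit pairs", {
  b <- spectra_block(rbind(c(1, 1, 1), c(3, 3, 3), c(5, 5, 5)),
                     grid = c(3, 2, 1),
                     sample_id = c("f1", "f1", "f2"),
                     cultivar = c("A", "A", "B"),
                     replicate = c(1L, 2L, 1L))
  avg <- average_replicates(b)
  expect_equal(unname(avg$X[1, ]), c(2, 2, 2))
  expect_equal(unname(avg$X[2, ]), c(5, 5, 5))   # single replicate passes through
  expect_equal(avg$cultivar, c("A", "B"))

  panel <- generate_lab_panel(n_per_cultivar = 54, seed = 6)
  sp <- generate_spectra(panel, grid_spec = c(10000, 4000, 41), seed = 6)
  expect_equal(nrow(average_replicates(sp)$X), 216)
})

test_that("preprocessing chains carry train-fitted statistics to new data", {
  set.seed(5)
  tr <- toy_block(n = 8, p = 60, seed = 5)
  te <- toy_block(n = 4, p = 60, seed = 6)
  te$X <- te$X + 5                               # gross shift
  spec <- preprocess_spec(list(list(name = "snv"),
                               list(name = "savgol", window = 9, polyorder = 2, deriv = 1),
                               list(name = "mean_center")))
  fitted <- fit_preprocess(spec, tr)
  out_te <- apply_preprocess(fitted$fitted, te)
  # train centers were used: re-centering the test output with its own means
  # must change it (the shift is only partially removed by SNV+derivative)
  ctr <- fitted$fitted$fits[[3]]$center
  manual <- savgol(snv(te), 9, 2, 1)
  expect_equal(out_te$X, sweep(manual$X, 2, ctr), tolerance = 1e-12,
               ignore_attr = TRUE)
  # applying the chain to the training block reproduces the fit output
  expect_equal(apply_preprocess(fitted$fitted, tr)$X, fitted$x$X,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(preprocess_spec(list(list(name = "wavelet"))), "unknown")
})
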