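#' Construct a lab panel object
#'
#' A lab panel is one row per fruit: identifiers, cultivar, harvest batch,
#' and the five quality-parameter values. Missing laboratory records are
#' `NA` in the value columns; the missing mask is derived from them.
#'
#' @param df data.frame with columns `sample_id`, `cultivar`, `harvest`
#'   and the five columns of [lab_params()].
#' @return object of class `lab_panel` (a data.frame).
#' @export
lab_panel <- function(df) {
  need <- c("sample_id", "cultivar", "harvest", lab_params())
  missing_cols <- setdiff(need, names(df))
  assert_that(length(missing_cols) == 0L,
              paste("lab panel missing columns:", paste(missing_cols, collapse = ", ")))
  assert_that(!anyDuplicated(df$sample_id), "one row per fruit: duplicated sample_id")
  vals <- as.matrix(df[lab_params()])
  assert_that(all(vals >= 0, na.rm = TRUE), "lab values must be non-negative where present")
  structure(as.data.frame(df)[need], class = c("lab_panel", "data.frame"))
}

#' Extract the numeric value matrix of a lab panel
#' @param panel a `lab_panel`.
#' @return numeric matrix (fruits x 5), `NA` where masked.
#' @export
lab_values <- function(panel) {
  m <- as.matrix(as.data.frame(panel)[lab_params()])
  rownames(m) <- panel$sample_id
  m
}

#' Missing mask of a lab panel
#' @param panel a `lab_panel`.
#' @return logical matrix, `TRUE` where the record is missing.
#' @export
missing_mask <- function(panel) is.na(lab_values(panel))

#' Complete-case subset of a lab panel
#' @param panel a `lab_panel`.
#' @return `lab_panel` with only fruits having all five records present.
#' @export
complete_panel <- function(panel) {
  keep <- rowSums(missing_mask(panel)) == 0L
  lab_panel(as.data.frame(panel)[keep, , drop = FALSE])
}

#' Simulate a laboratory quality panel
#'
#' Draws `n_per_cultivar` fruits per cultivar from a multivariate normal
#' with mean `lab_means` and covariance
#' `diag(cv * mean) %*% corr %*% diag(cv * mean)`, truncated at zero by
#' resampling offending fruits (keeps means unbiased for moderate CVs).
#' Fruits are split evenly over two harvests.
#'
#' @param profiles list of [cultivar_profile()] objects with distinct names.
#' @param n_per_cultivar fruits per cultivar (>= 1); the reference design
#'   is 54 (27 fruits x 2 harvests).
#' @param seed integer seed; the draw is fully reproducible.
#' @return a [lab_panel()] in cultivar-blocked order.
#' @export
generate_lab_panel <- function(profiles = default_profiles(), n_per_cultivar = 54L,
                               seed = 1L) {
  assert_that(length(profiles) >= 1L, "profiles must be non-empty")
  assert_that(all(vapply(profiles, inherits, TRUE, "cultivar_profile")),
              "profiles must be cultivar_profile objects")
  nms <- vapply(profiles, `[[`, "", "name")
  assert_that(!anyDuplicated(nms), "profiles must have distinct names")
  assert_that(n_per_cultivar >= 1L, "n_per_cultivar must be >= 1")
  set.seed(seed)
  n <- as.integer(n_per_cultivar)
  rows <- lapply(profiles, function(pr) {
    D <- diag(pr$lab_cvs * pr$lab_means, 5)
    Sigma <- D %*% pr$lab_corr %*% D
    V <- rmvnorm_psd(n, pr$lab_means, Sigma)
    for (it in seq_len(1000)) {          # resample fruits with any negative value
      bad <- which(apply(V < 0, 1, any))
      if (!length(bad)) break
      V[bad, ] <- rmvnorm_psd(length(bad), pr$lab_means, Sigma)
    }
    if (any(V < 0)) stop("truncation resampling failed for cultivar ", pr$name)
    colnames(V) <- lab_params()
    data.frame(sample_id = sprintf("%s_%03d", pr$name, seq_len(n)),
               cultivar = pr$name,
               # first half of each cultivar block = harvest 1, second = 2
               harvest = rep(1:2, each = ceiling(n / 2))[seq_len(n)],
               V)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  lab_panel(df)
}

#' Construct a spectra block
#'
#' @param X observations x wavenumbers absorbance matrix, all finite.
#' @param grid wavenumber vector (cm-1), strictly monotone descending,
#'   length equal to `ncol(X)`.
#' @param sample_id,cultivar per-row labels.
#' @param replicate per-row replicate index in `{1, 2}`.
#' @return object of class `spectra_block`.
#' @export
spectra_block <- function(X, grid, sample_id, cultivar, replicate) {
  X <- unname(as.matrix(X))   # labels live in the block fields, not dimnames
  assert_that(length(grid) == ncol(X), "grid length must equal ncol(X)")
  assert_that(all(diff(grid) < 0), "grid must be strictly monotone descending")
  assert_that(all(is.finite(X)), "absorbances must all be finite")
  assert_that(length(sample_id) == nrow(X) && length(cultivar) == nrow(X) &&
                length(replicate) == nrow(X), "label lengths must match nrow(X)")
  assert_that(all(replicate %in% c(1L, 2L)), "replicate must be 1 or 2")
  tab <- table(sample_id)
  assert_that(all(tab <= 2L), "at most two replicate rows per fruit")
  structure(list(X = X, grid = as.numeric(grid),
                 sample_id = as.character(sample_id),
                 cultivar = as.character(cultivar),
                 replicate = as.integer(replicate)),
            class = "spectra_block")
}

#' @export
print.spectra_block <- function(x, ...) {
  cat(sprintf("<spectra_block> %d observations x %d wavenumbers (%.0f to %.0f cm-1), %d fruits\n",
              nrow(x$X), ncol(x$X), max(x$grid), min(x$grid),
              length(unique(x$sample_id))))
  invisible(x)
}

#' @export
dim.spectra_block <- function(x) dim(x$X)

#' Default absorption-band model for the spectrum simulator
#'
#' Three Gaussian bands on a broad water baseline. The 6860 cm-1
#' combination band (O-H / C-H) is linked positively to soluble solids and
#' acidity; the 5188 cm-1 O-H band rides on a per-fruit latent water term
#' and is linked negatively to vitamin C, which aligns its amplitude with
#' the cultivar pairing observed in real spectra (the pair richer in
#' vitamin C shows the lower water band); the 8580 cm-1 C-H second
#' overtone is compositionally inert by default.
#'
#' @param separation between-cultivar band-amplitude contrast multiplier.
#'   The cultivar-mean part of each linked band amplitude is scaled by
#'   this factor while the fruit-to-fruit part (and scatter/noise) stays
#'   unchanged, so `separation = 5` makes the cultivar groups five times
#'   further apart in band-amplitude space at identical within-class
#'   variability.
#' @return list with elements `bands` (center/width/base/water_linked),
#'   `links` (bands x 5 coefficient matrix, absorbance units per parameter
#'   unit), `baseline` (broad water background), `water_sd` (sd of the
#'   latent water term around 1) and `separation`.
#' @export
default_band_model <- function(separation = 1) {
  p <- lab_params()
  bands <- data.frame(center = c(5188, 6860, 8580),
                      width  = c(180, 220, 260),
                      base   = c(0.45, 0.25, 0.12),
                      water_linked = c(TRUE, FALSE, FALSE))
  links <- matrix(0, nrow = 3, ncol = 5, dimnames = list(bands$center, p))
  links["6860", "ssc"]  <- 0.015   # AU per degree Brix
  links["6860", "ta"]   <- 0.08    # AU per % citric acid
  links["5188", "vitc"] <- -0.002  # AU per mg/100 g
  list(bands = bands, links = links,
       baseline = list(centers = c(5100, 6900), widths = c(900, 1100),
                       amps = c(0.50, 0.25)),
       water_sd = 0.03,
       separation = separation)
}

#' Simulate replicate FT-NIR spectra for a lab panel
#'
#' Each fruit's clean spectrum is a sum of Gaussian absorption bands whose
#' amplitudes are affine in the fruit's lab values (`base +
#' links %*% values`, water-linked bands additionally scaled by a latent
#' per-fruit water term), plus a broad water baseline. Two replicate rows
#' per fruit (the fruit rotated 180 degrees between scans) share the
#' composition signal and differ only through replicate-specific
#' multiplicative/additive scatter and iid noise:
#' `(1 + m) * clean + a + noise`.
#'
#' When the band model's `separation` differs from 1, the cultivar-mean
#' component of every linked band amplitude is scaled by it: the effective
#' lab values entering the links are
#' `v + (separation - 1) * profile_mean(cultivar)`, which widens the
#' between-cultivar contrast without touching within-cultivar variability,
#' scatter or noise.
#'
#' @param panel a [lab_panel()]; band-linked parameters must be present for
#'   every fruit.
#' @param profiles cultivar profiles supplying the means used by the
#'   `separation` scaling (default [default_profiles()]); only consulted
#'   when `separation != 1`.
#' @param grid_spec numeric `(start, end, n_points)` in cm-1; default
#'   `c(10000, 4000, 1557)`.
#' @param band_model see [default_band_model()].
#' @param scatter numeric `(multiplicative sd, additive sd)`.
#' @param noise_sd iid noise sd in absorbance units.
#' @param seed integer seed.
#' @return a [spectra_block()] with `2 * nrow(panel)` rows.
#' @export
generate_spectra <- function(panel, grid_spec = c(10000, 4000, 1557),
                             band_model = default_band_model(),
                             scatter = c(0.05, 0.02), noise_sd = 0.002,
                             seed = 1L, profiles = default_profiles()) {
  assert_that(grid_spec[3] >= 2, "n_points must be >= 2")
  grid <- seq(grid_spec[1], grid_spec[2], length.out = as.integer(grid_spec[3]))
  vals <- lab_values(panel)
  linked <- colnames(band_model$links)[colSums(abs(band_model$links)) > 0]
  bad <- panel$sample_id[rowSums(is.na(vals[, linked, drop = FALSE])) > 0]
  if (length(bad))
    stop("missing band-linked lab value for fruit(s): ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  bands <- band_model$bands
  inside <- bands$center >= min(grid) & bands$center <= max(grid)
  if (any(!inside)) {
    warning("band center(s) outside grid, skipped: ",
            paste(bands$center[!inside], collapse = ", "))
    keep <- which(inside)
  } else keep <- seq_len(nrow(bands))
  nf <- nrow(panel)
  set.seed(seed)
  water <- rnorm(nf, 1, band_model$water_sd)
  m <- rnorm(2L * nf, 0, scatter[1])
  a <- rnorm(2L * nf, 0, scatter[2])
  eps <- if (noise_sd > 0) matrix(rnorm(2L * nf * length(grid), 0, noise_sd),
                                  nrow = 2L * nf) else 0
  # band amplitudes: fruits x bands
  vals0 <- vals
  vals0[is.na(vals0)] <- 0   # non-linked missing values contribute nothing
  sep <- band_model$separation %||% 1
  if (sep != 1) {
    known <- vapply(profiles, `[[`, "", "name")
    miss <- setdiff(unique(panel$cultivar), known)
    if (length(miss))
      stop("separation scaling needs a profile for cultivar(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    mu <- t(vapply(panel$cultivar, function(cl)
      profiles[[match(cl, known)]]$lab_means, numeric(5)))
    vals0 <- vals0 + (sep - 1) * mu
  }
  amp <- matrix(rep(bands$base[keep], each = nf), nrow = nf)
  amp <- amp * ifelse(matrix(rep(bands$water_linked[keep], each = nf), nrow = nf),
                      water, 1)
  amp <- amp + vals0 %*% t(band_model$links[keep, , drop = FALSE])
  shapes <- t(vapply(keep, function(b)
    exp(-0.5 * ((grid - bands$center[b]) / bands$width[b])^2),
    numeric(length(grid))))
  bl <- band_model$baseline
  base_shape <- Reduce(`+`, lapply(seq_along(bl$centers), function(k)
    bl$amps[k] * exp(-0.5 * ((grid - bl$centers[k]) / bl$widths[k])^2)))
  clean <- amp %*% shapes + water %*% t(base_shape)
  idx <- rep(seq_len(nf), each = 2L)
  X <- (1 + m) * clean[idx, , drop = FALSE] + a + eps
  spectra_block(X, grid,
                sample_id = panel$sample_id[idx],
                cultivar = panel$cultivar[idx],
                replicate = rep(c(1L, 2L), nf))
}

#' Mask laboratory records for randomly chosen fruits
#'
#' Emulates real-world loss of laboratory measurements: exactly
#' `n_missing_fruits` fruits (chosen uniformly at random, i.e. missing
#' completely at random) get at least one quality parameter masked to
#' `NA`; all other rows are untouched.
#'
#' @param panel a [lab_panel()].
#' @param n_missing_fruits number of fruits to affect
#'   (0 <= n <= number of fruits).
#' @param seed integer seed.
#' @return the modified `lab_panel`.
#' @export
inject_missing <- function(panel, n_missing_fruits = 19L, seed = 1L) {
  assert_that(n_missing_fruits >= 0, "n_missing_fruits must be non-negative")
  assert_that(n_missing_fruits <= nrow(panel),
              "n_missing_fruits exceeds number of fruits")
  if (n_missing_fruits == 0L) return(panel)
  set.seed(seed)
  df <- as.data.frame(panel)
  rows <- sample(nrow(df), n_missing_fruits)
  for (r in rows) {
    k <- sample(5L, 1L)
    which_p <- sample(lab_params(), k)
    df[r, which_p] <- NA_real_
  }
  lab_panel(df)
}
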