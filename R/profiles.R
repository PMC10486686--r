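#' Names of the five laboratory quality parameters
#'
#' Order is fixed throughout the package: soluble solids content (ssc,
#' degrees Brix), titratable acidity (ta, % citric acid), vitamin C (vitc,
#' mg/100 g FW), anthocyanins (acy, mg/100 g FW), phenolic acids (phen,
#' mg/100 g FW).
#'
#' @return character vector of length 5.
#' @export
lab_params <- function() c("ssc", "ta", "vitc", "acy", "phen")

#' Construct a cultivar generation profile
#'
#' A profile holds the per-cultivar distribution of the five lab quality
#' parameters: mean vector, coefficients of variation, and the
#' within-cultivar correlation matrix. The implied covariance is
#' `diag(cv * mean) %*% corr %*% diag(cv * mean)`.
#'
#' @param name cultivar label.
#' @param lab_means named numeric vector of length 5 (see [lab_params()]),
#'   strictly positive.
#' @param lab_cvs coefficients of variation, length 5, all >= 0.
#' @param lab_corr 5x5 correlation matrix: symmetric, unit diagonal,
#'   positive semi-definite.
#' @return an object of class `cultivar_profile`.
#' @export
cultivar_profile <- function(name, lab_means, lab_cvs = rep(0.12, 5),
                             lab_corr = default_lab_corr()) {
  p <- lab_params()
  assert_that(is.character(name) && length(name) == 1L, "name must be a single string")
  assert_that(length(lab_means) == 5L && all(lab_means > 0),
              "lab_means must be 5 strictly positive values")
  assert_that(length(lab_cvs) == 5L && all(lab_cvs >= 0),
              "lab_cvs must be 5 non-negative values")
  lab_corr <- as.matrix(lab_corr)
  assert_that(all(dim(lab_corr) == c(5L, 5L)), "lab_corr must be 5x5")
  assert_that(max(abs(lab_corr - t(lab_corr))) < 1e-12, "lab_corr must be symmetric")
  assert_that(max(abs(diag(lab_corr) - 1)) < 1e-12, "lab_corr must have unit diagonal")
  if (min(eigen(lab_corr, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("lab_corr is not positive semi-definite", call. = FALSE)
  structure(list(name = name,
                 lab_means = setNames(as.numeric(lab_means), p),
                 lab_cvs = setNames(as.numeric(lab_cvs), p),
                 lab_corr = structure(lab_corr, dimnames = list(p, p))),
            class = "cultivar_profile")
}

#' Default within-cultivar correlation matrix for the lab panel
#'
#' Soluble solids and acidity are mildly coupled (fruit maturity),
#' anthocyanins and phenolic acids share biosynthetic origin; other pairs
#' are uncorrelated.
#'
#' @param ssc_ta correlation between SSC and TA (default 0.4).
#' @param acy_phen correlation between anthocyanins and phenolic acids
#'   (default 0.3).
#' @return 5x5 correlation matrix.
#' @export
default_lab_corr <- function(ssc_ta = 0.4, acy_phen = 0.3) {
  p <- lab_params()
  R <- diag(5)
  dimnames(R) <- list(p, p)
  R["ssc", "ta"] <- R["ta", "ssc"] <- ssc_ta
  R["acy", "phen"] <- R["phen", "acy"] <- acy_phen
  R
}

#' Default cultivar profiles for the four reference cultivars
#'
#' Mean quality-parameter values for Sibilla, Cristina, Romina and Silvia
#' (SSC in degrees Brix, TA in % citric acid, vitamin C / anthocyanins /
#' phenolic acids in mg/100 g FW). Fruit-to-fruit variability defaults to a
#' 12% coefficient of variation on every parameter.
#'
#' @param cv scalar coefficient of variation applied to all parameters.
#' @param lab_corr within-cultivar correlation matrix.
#' @return named list of four [cultivar_profile()] objects.
#' @export
default_profiles <- function(cv = 0.12, lab_corr = default_lab_corr()) {
  means <- list(
    Sibilla  = c(ssc = 7.66, ta = 0.75, vitc = 31.33, acy = 48.98, phen = 31.35),
    Cristina = c(ssc = 7.38, ta = 0.68, vitc = 14.31, acy = 38.98, phen = 19.16),
    Romina   = c(ssc = 6.15, ta = 0.48, vitc = 31.84, acy = 93.81, phen = 21.03),
    Silvia   = c(ssc = 4.83, ta = 0.65, vitc = 15.64, acy = 61.00, phen = 29.17))
  lapply(names(means), function(nm)
    cultivar_profile(nm, means[[nm]], lab_cvs = rep(cv, 5), lab_corr = lab_corr)) |>
    setNames(names(means))
}

#' @export
print.cultivar_profile <- function(x, ...) {
  cat("<cultivar_profile>", x$name, "\n")
  print(rbind(mean = x$lab_means, cv = x$lab_cvs))
  invisible(x)
}
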