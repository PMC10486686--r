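# One-way ANOVA with Tukey HSD post hoc comparisons and a compact letter
# display, as used to compare cultivar means of the lab quality parameters.

#' One-way analysis of variance with Tukey HSD pairwise comparisons
#'
#' Classical equal-variance decomposition: `F = MS_between / MS_within`
#' with the p value from the F distribution. Pairwise comparisons use the
#' Tukey(-Kramer) studentized range statistic, valid for unbalanced groups.
#' Missing values are dropped.
#'
#' @param values numeric vector.
#' @param groups group label per value (>= 2 groups, each with >= 2
#'   observations after NA removal).
#' @return object of class `anova_result`: `F`, `p`, `df`, `means`, `se`,
#'   `n`, and `tukey` (data.frame of pairwise mean differences and
#'   adjusted p values).
#' @export
anova_oneway <- function(values, groups) {
  keep <- !is.na(values)
  values <- values[keep]; groups <- as.character(groups)[keep]
  tab <- table(groups)
  assert_that(length(tab) >= 2, "need at least two groups")
  if (any(tab < 2)) stop("group(s) with fewer than 2 observations: ",
                         paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)
  g <- names(tab)
  n <- as.integer(tab[g])
  means <- vapply(g, function(x) mean(values[groups == x]), 0)
  sds <- vapply(g, function(x) sd(values[groups == x]), 0)
  N <- length(values); k <- length(g)
  grand <- mean(values)
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum((values - means[groups])^2)
  dfb <- k - 1L; dfw <- N - k
  msb <- ssb / dfb; msw <- ssw / dfw
  # convention for degenerate data: zero between-group variation gives F = 0
  # even when the within-group variance is also zero
  Fstat <- if (ssb == 0) 0 else msb / msw
  pval <- pf(Fstat, dfb, dfw, lower.tail = FALSE)
  pairs <- t(utils::combn(g, 2))
  tk <- data.frame(group1 = pairs[, 1], group2 = pairs[, 2])
  tk$diff <- means[tk$group1] - means[tk$group2]
  se_pair <- sqrt(msw / 2 * (1 / n[match(tk$group1, g)] + 1 / n[match(tk$group2, g)]))
  tk$q <- abs(tk$diff) / se_pair
  tk$p <- ptukey(tk$q, nmeans = k, df = dfw, lower.tail = FALSE)
  rownames(tk) <- NULL
  structure(list(F = Fstat, p = pval, df = c(between = dfb, within = dfw),
                 means = means, se = sds / sqrt(n), n = setNames(n, g),
                 ms_within = msw, tukey = tk),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> F(%d, %d) = %.3f, p = %.3g\n",
              x$df["between"], x$df["within"], x$F, x$p))
  print(round(rbind(mean = x$means, se = x$se), 3))
  invisible(x)
}

#' Compact letter display from Tukey HSD comparisons
#'
#' Assigns letters by the standard insert-and-absorb procedure so that two
#' groups share a letter if and only if their Tukey-adjusted p value is at
#' least `alpha`. Groups are ordered by descending mean, so letter "a"
#' marks the largest mean.
#'
#' @param result an [anova_oneway()] result.
#' @param alpha significance level (default 0.05).
#' @return named character vector of letter strings, ordered by descending
#'   group mean.
#' @export
tukey_letters <- function(result, alpha = 0.05) {
  g <- names(sort(result$means, decreasing = TRUE))
  sig <- matrix(FALSE, length(g), length(g), dimnames = list(g, g))
  for (i in seq_len(nrow(result$tukey))) {
    r <- result$tukey[i, ]
    if (r$p < alpha) sig[r$group1, r$group2] <- sig[r$group2, r$group1] <- TRUE
  }
  sets <- list(g)                       # each set = groups sharing one letter
  for (a in seq_along(g)) for (b in seq_len(length(g))) {
    if (b <= a || !sig[g[a], g[b]]) next
    for (s in seq_along(sets)) {
      cur <- sets[[s]]
      if (all(c(g[a], g[b]) %in% cur)) {
        sets[[s]] <- setdiff(cur, g[a])
        sets[[length(sets) + 1L]] <- setdiff(cur, g[b])
      }
    }
    # absorb sets contained in another set
    keep <- vapply(seq_along(sets), function(i)
      !any(vapply(seq_along(sets), function(j)
        i != j && all(sets[[i]] %in% sets[[j]]) &&
          !(j < i && identical(sets[[i]], sets[[j]])), TRUE)), TRUE)
    sets <- sets[keep]
  }
  # order letters by the position of their first (largest-mean) group
  sets <- sets[order(vapply(sets, function(s) min(match(s, g)), 0))]
  out <- setNames(rep("", length(g)), g)
  for (s in seq_along(sets))
    out[sets[[s]]] <- paste0(out[sets[[s]]], letters[s])
  out
}
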