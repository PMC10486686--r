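# Multiblock data fusion of the laboratory panel (D-Lab) and spectral
# (D-NIR) blocks. Low level concatenates pretreated variables after block
# scaling; mid level concatenates per-block PCA scores after autoscaling.
# All fitted statistics are stored so new samples are fused with training
# statistics only.

new_fused_block <- function(X, block_map, level, stats) {
  structure(list(X = X, block_map = block_map, level = level, stats = stats),
            class = "fused_block")
}

#' @export
print.fused_block <- function(x, ...) {
  cat(sprintf("<fused_block level=%s> %d x %d (%s)\n", x$level,
              nrow(x$X), ncol(x$X),
              paste(table(x$block_map$block), collapse = " + ")))
  invisible(x)
}

check_blocks <- function(blocks) {
  assert_that(length(blocks) >= 1, "at least one block required")
  blocks <- lapply(blocks, as.matrix)
  if (is.null(names(blocks)) || any(names(blocks) == ""))
    names(blocks) <- paste0("block", seq_along(blocks))
  nr <- vapply(blocks, nrow, 0L)
  if (length(unique(nr)) != 1)
    stop("row-count mismatch between blocks: ",
         paste(sprintf("%s=%d", names(blocks), nr), collapse = ", "), call. = FALSE)
  blocks
}

#' Low-level fusion of pretreated data blocks
#'
#' Concatenates the blocks column-wise, block-scales each to unit total
#' variance (so no block dominates through sheer width), then mean centers.
#' Scale factors and column means are stored for fusing new samples.
#'
#' @param blocks named list of pretreated matrices with aligned rows.
#' @return a `fused_block` (level `"low"`) whose `block_map` records each
#'   fused column's source block and source-variable index.
#' @export
low_level_fuse <- function(blocks) {
  blocks <- check_blocks(blocks)
  scaled <- block_scale(blocks)
  X <- do.call(cbind, scaled)
  X <- mean_center(X)
  block_map <- data.frame(
    block = rep(names(blocks), vapply(blocks, ncol, 0L)),
    index = unlist(lapply(blocks, function(B) seq_len(ncol(B)))))
  new_fused_block(`attributes<-`(X, list(dim = dim(X))), block_map, "low",
                  stats = list(factors = attr(scaled, "factors"),
                               center = attr(X, "center")))
}

#' Mid-level fusion via per-block PCA scores
#'
#' Fits a PCA per block (centered, not scaled: blocks are assumed already
#' pretreated, e.g. the lab block autoscaled and the spectral block
#' derivative-treated), retains the requested number of score columns from
#' each, concatenates, and autoscales the fused features. Per-block PCA
#' models and the autoscale statistics are stored so new samples can be
#' fused with training statistics.
#'
#' @param blocks named list of pretreated matrices with aligned rows.
#' @param n_scores integer vector, scores to retain per block (default 5
#'   each).
#' @param autoscale_fused autoscale the concatenated scores (default TRUE).
#' @return a `fused_block` (level `"mid"`); `block_map$index` is the
#'   source-component index.
#' @export
mid_level_fuse <- function(blocks, n_scores = rep(5L, length(blocks)),
                           autoscale_fused = TRUE) {
  blocks <- check_blocks(blocks)
  assert_that(length(n_scores) == length(blocks),
              "n_scores must have one entry per block")
  models <- Map(function(B, k) {
    kmax <- min(nrow(B) - 1L, ncol(B))
    if (k > kmax)
      stop(sprintf("requested %d scores but block rank is at most %d", k, kmax),
           call. = FALSE)
    fit_pca(B, n_components = k, center = TRUE, scale = FALSE)
  }, blocks, as.integer(n_scores))
  scores <- do.call(cbind, lapply(models, `[[`, "T"))
  colnames(scores) <- unlist(Map(function(nm, k) sprintf("%s_pc%d", nm, seq_len(k)),
                                 names(blocks), as.integer(n_scores)))
  stats <- list(models = models, n_scores = as.integer(n_scores),
                autoscale_fused = autoscale_fused)
  if (autoscale_fused) {
    scores <- autoscale(scores)
    stats$center <- attr(scores, "center")
    stats$scale <- attr(scores, "scale")
  }
  block_map <- data.frame(
    block = rep(names(blocks), as.integer(n_scores)),
    index = unlist(lapply(as.integer(n_scores), seq_len)))
  new_fused_block(`attributes<-`(scores, list(dim = dim(scores),
                                              dimnames = dimnames(scores))),
                  block_map, "mid", stats)
}

#' Fuse new samples with a previously fitted fusion
#'
#' @param fused a `fused_block` from [low_level_fuse()] or
#'   [mid_level_fuse()].
#' @param blocks list of new-data matrices in the same order as at fit
#'   time.
#' @return fused feature matrix for the new samples (training statistics
#'   only; nothing is refitted).
#' @export
apply_fusion <- function(fused, blocks) {
  blocks <- check_blocks(blocks)
  if (fused$level == "low") {
    scaled <- block_scale(blocks, factors = fused$stats$factors)
    mean_center(do.call(cbind, scaled), center = fused$stats$center)
  } else {
    scores <- do.call(cbind, Map(project, fused$stats$models, blocks))
    if (fused$stats$autoscale_fused)
      scores <- autoscale(scores, center = fused$stats$center,
                          scale = fused$stats$scale)
    scores
  }
}

#' Back-reconstruct original-variable contributions of a fused-space PCA
#'
#' For a PCA fitted on mid-level fused features, expresses each fused-space
#' component in terms of the original variables of every block. The
#' transfer matrix `F` maps fused features to original variables: the row
#' for block k's component j carries block k's loading vector j (zero on
#' other blocks' variables), divided by that fused column's autoscale
#' standard deviation so that `T_fused %*% O` back-projects the variables
#' that actually entered the fused PCA. The contribution matrix is
#' `O = t(P) %*% F`.
#'
#' @param fused_model `pca_model` fitted on the fused feature matrix.
#' @param block_loadings list of per-block loading matrices (variables x
#'   retained components) from the block PCAs.
#' @param fused_scales autoscale sds of the fused columns (default 1s).
#' @return object of class `contribution_matrix`: `O` (fused components x
#'   total original variables) and `blocks` (source block per column).
#' @export
reconstruct_contributions <- function(fused_model, block_loadings,
                                      fused_scales = NULL) {
  ks <- vapply(block_loadings, ncol, 0L)
  ps <- vapply(block_loadings, nrow, 0L)
  assert_that(sum(ks) == nrow(fused_model$P),
              sprintf("fused PCA has %d features but block loadings supply %d",
                      nrow(fused_model$P), sum(ks)))
  fused_scales <- fused_scales %||% rep(1, sum(ks))
  assert_that(length(fused_scales) == sum(ks),
              "fused_scales must have one entry per fused feature")
  if (is.null(names(block_loadings)))
    names(block_loadings) <- paste0("block", seq_along(block_loadings))
  Fm <- matrix(0, nrow = sum(ks), ncol = sum(ps))
  row0 <- cumsum(c(0L, ks))
  col0 <- cumsum(c(0L, ps))
  for (b in seq_along(block_loadings))
    Fm[row0[b] + seq_len(ks[b]), col0[b] + seq_len(ps[b])] <- t(block_loadings[[b]])
  Fm <- Fm / fused_scales
  structure(list(O = t(fused_model$P) %*% Fm,
                 blocks = rep(names(block_loadings), ps)),
            class = "contribution_matrix")
}
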