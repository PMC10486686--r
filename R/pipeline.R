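# End-to-end orchestration: a single classification experiment (run_mode)
# and the full reproducible analysis bundle (run_pipeline).

#' Configuration for a classification experiment
#'
#' @param trim analysis range in cm-1 (default 4000-9000).
#' @param sg Savitzky-Golay settings (window, polyorder, deriv); the
#'   default chain is the first derivative, window 9, order 2.
#' @param n_test external test-set size; `NULL` picks
#'   `round(n * 60 / 197)`, reproducing a 137/60 split at n = 197.
#' @param segments venetian-blinds CV segments (default 5).
#' @param lv_grid candidate latent-variable counts (default 1:10).
#' @param n_scores per-block retained PCA scores for mid-level fusion
#'   (default 5 + 5).
#' @param threshold `"roc"` for the CV-error-minimizing threshold, or a
#'   fixed numeric value such as 0.5.
#' @return a list of settings for [run_mode()].
#' @export
mode_config <- function(trim = c(4000, 9000),
                        sg = list(window = 9L, polyorder = 2L, deriv = 1L),
                        n_test = NULL, segments = 5L, lv_grid = 1:10,
                        n_scores = c(5L, 5L), threshold = "roc") {
  list(trim = trim, sg = sg, n_test = n_test, segments = segments,
       lv_grid = lv_grid, n_scores = n_scores, threshold = threshold)
}

# cross-validated continuous predictions for every LV count in one fit per
# fold; returns n x A matrix (binary) or n x classes x A array (multi)
cv_pls_predictions <- function(X, Y, folds, max_lv) {
  n <- nrow(X); m <- ncol(Y)
  A <- max_lv
  preds <- array(NA_real_, dim = c(n, m, A))
  for (f in sort(unique(folds))) {
    hold <- folds == f
    core <- pls_core(X[!hold, , drop = FALSE], Y[!hold, , drop = FALSE],
                     n_lv = max_lv)
    Xc <- sweep(X[hold, , drop = FALSE], 2, core$center_x)
    for (a in seq_len(core$n_lv))
      preds[hold, , a] <- Xc %*% core$B[, , a] +
        matrix(core$center_y, sum(hold), m, byrow = TRUE)
    if (core$n_lv < A)
      for (a in seq(core$n_lv + 1L, A)) preds[hold, , a] <- preds[hold, , core$n_lv]
  }
  preds
}

fold_errors <- function(err_per_sample, folds) {
  fe <- vapply(sort(unique(folds)), function(f) mean(err_per_sample[folds == f]), 0)
  c(mean = mean(err_per_sample), se = sd(fe) / sqrt(length(fe)))
}

#' Run one complete PLS-DA classification experiment
#'
#' Full pipeline on linked spectra and lab panel: average the two NIR
#' replicates per fruit, complete-case join, spectral pretreatment
#' (trim + Savitzky-Golay derivative), duplex train/test split on the
#' pretreated spectra, optional mid-level fusion (block PCAs and scaling
#' fitted on training samples only), venetian-blinds cross-validation over
#' the latent-variable grid, one-standard-error LV selection, decision
#' threshold chosen on CV predictions, final refit on the training set and
#' evaluation on both the CV and external-test predictions.
#'
#' @param spectra a [spectra_block()] (two replicates per fruit).
#' @param panel the matching [lab_panel()] (may contain missing records).
#' @param mode a [mode_spec()] from [plsda_modes()] (binary or `multi`).
#' @param feature_set `"nir"` (spectra only) or `"fused"` (mid-level
#'   fusion of lab + spectra).
#' @param config a [mode_config()].
#' @return a `classification_report`: selected LVs, threshold, CV and
#'   external-test metrics (TPR/TNR/FPR/error/AUC for binary modes,
#'   per-class accuracy for the multiclass model), split sizes and the
#'   per-LV CV error profile.
#' @export
run_mode <- function(spectra, panel, mode, feature_set = c("nir", "fused"),
                     config = mode_config()) {
  feature_set <- match.arg(feature_set)
  multi <- inherits(mode, "mode_spec_multi")
  avg <- average_replicates(spectra)
  j <- join_blocks(avg, panel, complete_case = TRUE)
  n <- nrow(j$spectra$X)
  assert_that(n >= 20, "need at least 20 complete-case samples")
  labels <- j$spectra$cultivar
  if (!multi) {
    known <- labels %in% c(mode$positive, mode$negative)
    assert_that(all(known), "cultivar labels outside the mode's class sets")
    y <- as.numeric(labels %in% mode$positive)
    assert_that(length(unique(y)) == 2, "both mode classes must be present")
  }
  nir <- trim_range(j$spectra, config$trim[1], config$trim[2])
  nir <- savgol(nir, config$sg$window, config$sg$polyorder, config$sg$deriv)
  M <- nir$X
  n_test <- config$n_test %||% round(n * 60 / 197)
  split <- duplex_split(M, n_test, autoscale = FALSE)
  tr <- split$train; te <- split$test
  if (feature_set == "nir") {
    Xtr <- M[tr, , drop = FALSE]
    Xte <- M[te, , drop = FALSE]
    fused <- NULL
  } else {
    L <- lab_values(j$panel)
    Ltr <- autoscale(L[tr, , drop = FALSE])
    Lte <- autoscale(L[te, , drop = FALSE], center = attr(Ltr, "center"),
                     scale = attr(Ltr, "scale"))
    fused <- mid_level_fuse(list(lab = Ltr, nir = M[tr, , drop = FALSE]),
                            n_scores = config$n_scores)
    Xtr <- fused$X
    Xte <- apply_fusion(fused, list(Lte, M[te, , drop = FALSE]))
  }
  folds <- venetian_blinds(length(tr), config$segments)
  max_lv <- min(max(config$lv_grid), nrow(Xtr) - 1L, ncol(Xtr))
  grid <- config$lv_grid[config$lv_grid <= max_lv]
  if (multi) {
    classes <- sort(unique(labels))
    Ytr <- outer(labels[tr], classes, `==`) * 1
    preds <- cv_pls_predictions(Xtr, Ytr, folds, max_lv)
    errs <- vapply(grid, function(a) {
      wrong <- classes[max.col(preds[, , a], ties.method = "first")] != labels[tr]
      fold_errors(wrong, folds)
    }, c(mean = 0, se = 0))
    a_star <- grid[select_lvs(errs["mean", ], errs["se", ])]
    cv_class <- classes[max.col(preds[, , a_star], ties.method = "first")]
    model <- fit_multiclass(Xtr, labels[tr], n_lv = a_star)
    te_class <- predict_multiclass(model, Xte)
    per_class <- function(truth, pred) {
      vapply(classes, function(cl) 100 * mean(pred[truth == cl] == cl), 0)
    }
    rep_cv <- list(per_class_accuracy = per_class(labels[tr], cv_class),
                   error = 100 * mean(cv_class != labels[tr]))
    rep_te <- list(per_class_accuracy = per_class(labels[te], te_class),
                   error = 100 * mean(te_class != labels[te]))
    threshold <- NA_real_
  } else {
    preds <- cv_pls_predictions(Xtr, matrix(y[tr]), folds, max_lv)
    errs <- vapply(grid, function(a)
      fold_errors((preds[, 1, a] >= 0.5) != (y[tr] == 1), folds),
      c(mean = 0, se = 0))
    a_star <- grid[select_lvs(errs["mean", ], errs["se", ])]
    cv_score <- preds[, 1, a_star]
    threshold <- if (identical(config$threshold, "roc"))
      choose_threshold(y[tr], cv_score) else as.numeric(config$threshold)
    model <- fit_plsda(Xtr, labels[tr], mode, n_lv = a_star, threshold = threshold)
    te_score <- predict_scores(model, Xte)
    rep_cv <- c(evaluate(y[tr], as.integer(cv_score >= threshold)),
                auc = roc_curve(y[tr], cv_score)$auc)
    rep_te <- c(evaluate(y[te], as.integer(te_score >= threshold)),
                auc = if (length(unique(y[te])) == 2)
                  roc_curve(y[te], te_score)$auc else NA_real_)
  }
  structure(list(mode = mode$id, feature_set = feature_set,
                 n_lv = a_star, threshold = threshold,
                 positive = if (multi) NULL else mode$positive,
                 n_train = length(tr), n_test = length(te),
                 cv = rep_cv, test = rep_te,
                 lv_grid = grid, lv_errors = 100 * errs["mean", ],
                 lv_se = 100 * errs["se", ],
                 split = split, model = model),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> %s / %s: %d LVs, %d train / %d test\n",
              x$mode, x$feature_set, x$n_lv, x$n_train, x$n_test))
  if (!is.null(x$cv$tpr)) {
    cat(sprintf("  CV:   TNR %5.1f  TPR %5.1f  error %5.1f  AUC %.3f\n",
                x$cv$tnr, x$cv$tpr, x$cv$error, x$cv$auc))
    cat(sprintf("  test: TNR %5.1f  TPR %5.1f  error %5.1f\n",
                x$test$tnr, x$test$tpr, x$test$error))
  } else {
    cat("  CV per-class %:  ",
        paste(sprintf("%s %.1f", names(x$cv$per_class_accuracy),
                      x$cv$per_class_accuracy), collapse = ", "), "\n")
    cat("  test per-class %:",
        paste(sprintf("%s %.1f", names(x$test$per_class_accuracy),
                      x$test$per_class_accuracy), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Full analysis configuration
#'
#' One document holding every stage's parameters; all randomness flows
#' from the single root `seed` through per-stage derived substreams.
#' Round-trips losslessly through JSON ([write_config()] /
#' [read_config()]).
#'
#' @param seed root seed.
#' @param n_per_cultivar fruits per cultivar (default 54).
#' @param n_missing fruits with injected missing lab records (default 19,
#'   so 216 fruits reduce to 197 complete cases).
#' @param cv generator coefficient of variation for the lab values.
#' @param grid spectral grid `(start, end, n_points)` in cm-1.
#' @param scatter multiplicative/additive scatter sds.
#' @param noise_sd iid spectral noise sd (absorbance units).
#' @param separation between-cultivar band-amplitude contrast multiplier (see
#'   [default_band_model()]).
#' @param modes classification modes to run (subset of names of
#'   [plsda_modes()]).
#' @param features feature sets to run (`"nir"`, `"fused"`).
#' @param ... overrides passed to [mode_config()].
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(seed = 1L, n_per_cultivar = 54L, n_missing = 19L,
                            cv = 0.12, grid = c(10000, 4000, 1557),
                            scatter = c(0.05, 0.02), noise_sd = 0.002,
                            separation = 1, modes = c("mode1", "mode2", "mode3", "multi"),
                            features = "nir", ...) {
  structure(list(seed = as.integer(seed), n_per_cultivar = as.integer(n_per_cultivar),
                 n_missing = as.integer(n_missing), cv = cv, grid = grid,
                 scatter = scatter, noise_sd = noise_sd, separation = separation,
                 modes = modes, features = features,
                 mode_config = mode_config(...)),
            class = "analysis_config")
}

#' Serialize / deserialize an analysis configuration as JSON
#' @param config an [analysis_config()].
#' @param path JSON file path.
#' @return `read_config` returns the `analysis_config`; `write_config`
#'   returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- analysis_config()
  for (nm in setdiff(names(raw), "mode_config")) cfg[[nm]] <- raw[[nm]]
  if (!is.null(raw$mode_config))
    cfg$mode_config <- utils::modifyList(cfg$mode_config, raw$mode_config)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Run the complete analysis pipeline
#'
#' Simulates the lab panel and linked spectra, injects missing laboratory
#' records, and runs every analysis stage: per-parameter one-way ANOVA
#' with Tukey letters, PCA of the lab, spectral and mid-level fused
#' blocks (with contribution back-reconstruction), and the configured
#' PLS-DA classification experiments. Fully reproducible from
#' `(config, seed)`; when `outdir` is given, all tables are written as
#' CSV/JSON with the config hash and seed in each file name.
#'
#' @param config an [analysis_config()].
#' @param outdir optional output directory.
#' @return a report bundle: `panel`, `spectra`, `anova`, `pca`,
#'   `classification` (one report per mode x feature set), `shapes`
#'   (stage-by-stage dataset sizes) and `hash`.
#' @export
run_pipeline <- function(config = analysis_config(), outdir = NULL) {
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", what, conditionMessage(e)),
           call. = FALSE))
  }
  hash <- substr(config_hash(unclass(config)), 1, 8)
  panel0 <- stage("simulate-panel",
                  generate_lab_panel(default_profiles(cv = config$cv),
                                     config$n_per_cultivar,
                                     seed = derive_seed(config$seed, 1L)))
  spectra <- stage("simulate-spectra",
                   generate_spectra(panel0, grid_spec = config$grid,
                                    band_model = default_band_model(config$separation),
                                    scatter = config$scatter,
                                    noise_sd = config$noise_sd,
                                    seed = derive_seed(config$seed, 2L)))
  panel <- stage("inject-missing",
                 inject_missing(panel0, config$n_missing,
                                seed = derive_seed(config$seed, 3L)))
  vals <- lab_values(panel)
  anova_results <- stage("anova", lapply(setNames(nm = lab_params()), function(p) {
    res <- anova_oneway(vals[, p], panel$cultivar)
    list(result = res, letters = tukey_letters(res))
  }))
  # observation-level complete-case join (each fruit's lab row duplicated
  # across its two replicate spectra)
  jo <- stage("join", join_blocks(spectra, panel, complete_case = TRUE))
  obs_lab <- lab_values(jo$panel)[match(jo$spectra$sample_id, jo$panel$sample_id), ,
                                  drop = FALSE]
  pp <- stage("preprocess", fit_preprocess(default_nir_preprocess(), jo$spectra))
  pca_lab <- stage("pca-lab", fit_pca(autoscale(obs_lab), n_components = 5))
  pca_nir <- stage("pca-nir", fit_pca(pp$x$X, n_components = 5))
  fused <- stage("fusion", mid_level_fuse(list(lab = autoscale(obs_lab),
                                               nir = pp$x$X),
                                          n_scores = c(5L, 5L)))
  pca_fused <- stage("pca-fused", fit_pca(fused$X, n_components = 5))
  contrib <- stage("contributions",
                   reconstruct_contributions(pca_fused,
                                             lapply(fused$stats$models, `[[`, "P"),
                                             fused_scales = fused$stats$scale))
  modes <- plsda_modes()
  jobs <- expand.grid(mode = config$modes, feature = config$features,
                      stringsAsFactors = FALSE)
  reports <- stage("classification", lapply(seq_len(nrow(jobs)), function(i)
    run_mode(spectra, panel, modes[[jobs$mode[i]]],
             feature_set = jobs$feature[i], config = config$mode_config)))
  names(reports) <- paste(jobs$mode, jobs$feature, sep = "_")
  shapes <- list(observations = nrow(spectra$X),
                 wavenumbers = ncol(spectra$X),
                 fruits = nrow(panel),
                 complete_fruits = nrow(jo$panel),
                 complete_observations = nrow(jo$spectra$X),
                 train = if (length(reports)) reports[[1]]$n_train else NA,
                 test = if (length(reports)) reports[[1]]$n_test else NA)
  bundle <- list(config = config, hash = hash, panel = panel, spectra = spectra,
                 anova = anova_results,
                 pca = list(lab = pca_lab, nir = pca_nir, fused = pca_fused,
                            contributions = contrib),
                 classification = reports, shapes = shapes)
  if (!is.null(outdir)) write_bundle(bundle, outdir)
  bundle
}

write_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tag <- sprintf("%s_seed%d", bundle$hash, bundle$config$seed)
  fp <- function(name, ext) file.path(outdir, sprintf("%s_%s.%s", name, tag, ext))
  write_lab_csv(bundle$panel, fp("lab_panel", "csv"))
  write_spectra_csv(bundle$spectra, fp("spectra", "csv"))
  anova_tab <- do.call(rbind, lapply(names(bundle$anova), function(p) {
    a <- bundle$anova[[p]]
    data.frame(parameter = p, cultivar = names(a$result$means),
               mean = a$result$means, se = a$result$se,
               letters = a$letters[names(a$result$means)])
  }))
  data.table::fwrite(anova_tab, fp("anova", "csv"))
  cls <- do.call(rbind, lapply(bundle$classification, function(r) {
    if (!is.null(r$cv$tpr))
      data.frame(model = r$mode, features = r$feature_set, LVs = r$n_lv,
                 cv_TNR = r$cv$tnr, cv_TPR = r$cv$tpr, cv_error = r$cv$error,
                 val_TNR = r$test$tnr, val_TPR = r$test$tpr,
                 val_error = r$test$error)
    else
      data.frame(model = r$mode, features = r$feature_set, LVs = r$n_lv,
                 cv_TNR = NA, cv_TPR = NA, cv_error = r$cv$error,
                 val_TNR = NA, val_TPR = NA, val_error = r$test$error)
  }))
  if (!is.null(cls)) data.table::fwrite(cls, fp("classification", "csv"))
  jsonlite::write_json(bundle$shapes, fp("shapes", "json"), auto_unbox = TRUE)
  write_config(bundle$config, fp("config", "json"))
  invisible(outdir)
}
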