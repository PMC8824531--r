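# Cross-validated pipeline evaluation, balanced accuracy, permutation
# chance levels, and runtime accounting.

#' Balanced accuracy (mean per-class recall)
#'
#' @param true true class labels (every class must be represented).
#' @param pred predicted labels, same length.
#' @return proportion in `[0, 1]`.
#' @export
balanced_accuracy <- function(true, pred) {
  abort_if(length(true) != length(pred),
           "label vectors differ in length (%d vs %d)",
           length(true), length(pred))
  classes <- sort(unique(true))
  rec <- vapply(classes, function(cl) {
    sel <- true == cl
    abort_if(!any(sel), "class %s has no trials", cl)
    mean(pred[sel] == cl)
  }, numeric(1))
  mean(rec)
}

# Resolve an input (epoch_set | band_power | feature_matrix | matrix) to
# the internal dataset abstraction used by the CV driver.
as_dataset <- function(x, labels = NULL, grid = NULL, rmap = NULL,
                       families = FEATURE_FAMILIES, bands = default_bands(),
                       freqs = default_freqs(), n_cycles = 5,
                       fs_out = 50.25, n_bins = 5, ar_order = 4,
                       norm_pool = "train") {
  if (inherits(x, "epoch_set")) {
    if (is.null(grid)) grid <- make_window_grid()
    if (is.null(rmap)) rmap <- default_region_map(x$channel_names)
    crop <- c(min(grid$windows[, 1]), max(grid$windows[, 2]))
    tfr <- morlet_transform(x, freqs, n_cycles, fs_out, crop_ms = crop)
    x <- aggregate_band_power(tfr, bands)
  }
  if (inherits(x, "band_power")) {
    if (is.null(rmap) &&
        any(c("correlation", "phase_sync", "ar") %in% families)) {
      rmap <- default_region_map(x$channel_names)
    }
    abort_if(x$normalized && norm_pool == "train",
             paste("leakage guard: band power was normalized outside the",
                   "training fold; pass unnormalized power (or use",
                   "norm_pool = 'all' for the whole-set mode)"))
    if (is.null(grid)) grid <- make_window_grid()
    return(list(kind = "bandpower", bpw = x, grid = grid, rmap = rmap,
                labels = labels %||% x$labels, families = families,
                n_bins = n_bins, ar_order = ar_order, norm_pool = norm_pool))
  }
  if (inherits(x, "feature_matrix")) {
    return(list(kind = "features", X = x$X, labels = labels %||% x$labels))
  }
  abort_if(!is.matrix(x), "unsupported input type")
  abort_if(is.null(labels), "labels required with a plain matrix")
  list(kind = "features", X = x, labels = labels)
}

# Per-fold feature construction. Returns list(X = base matrix,
# csp_augment = NULL or function(labels_bin, train_idx) -> csp columns).
fold_features <- function(ds, train_idx, binary_labels = NULL) {
  if (ds$kind == "features") {
    return(list(X = ds$X, csp_augment = NULL))
  }
  fams <- setdiff(ds$families, "csp")
  pool <- if (ds$norm_pool == "train") train_idx else seq_len(dim(ds$bpw$bp)[1])
  bpw_n <- normalize_band_power(ds$bpw, pool)
  base <- if (length(fams) > 0) {
    extract_features(bpw_n, ds$grid, ds$rmap, train_idx, fams,
                     ds$n_bins, ds$ar_order)
  } else NULL
  aug <- NULL
  if ("csp" %in% ds$families) {
    grid <- ds$grid; rmap <- ds$rmap
    aug <- function(labels_bin, tr_idx) {
      model <- fit_csp(bpw_n, grid, tr_idx, labels_bin)
      extract_csp_features(bpw_n, grid, model)
    }
  }
  list(X = if (is.null(base)) NULL else base$X, csp_augment = aug)
}

#' Cross-validated evaluation of the full decoding pipeline
#'
#' Stratified outer k-fold evaluation. Within each training fold, in
#' order: normalization statistics, CSP fitting, feature selection,
#' SMOTE, classifier training; the test fold is transformed with
#' training-fold statistics only. Accepts an [epoch_set()],
#' an unnormalized `band_power`, a `feature_matrix`, or a plain matrix
#' plus labels. Binary problems run the plain pipeline; with 3 or more
#' classes `multiclass` picks the generalization scheme.
#'
#' @param x input data (see above).
#' @param cfg a [pipeline_config()].
#' @param labels required for plain matrices.
#' @param outer_folds outer CV folds (default 5).
#' @param multiclass `"tree"` (default) or `"voting"`; ignored for
#'   binary labels.
#' @param min_trials per-class minimum (default 20).
#' @param seed outer fold seed (default: `cfg$seed`).
#' @param grid,rmap,families,norm_pool forwarded to feature extraction
#'   for epoch/band-power inputs.
#' @return an `evaluation_report`: per-fold and mean balanced accuracy,
#'   per-fold selection and balancing logs, runtime per stage, config
#'   echo.
#' @export
cross_validate_pipeline <- function(x, cfg = pipeline_config(),
                                    labels = NULL, outer_folds = 5,
                                    multiclass = c("tree", "voting"),
                                    min_trials = 20, seed = NULL,
                                    grid = NULL, rmap = NULL,
                                    families = FEATURE_FAMILIES,
                                    norm_pool = "train") {
  multiclass <- match.arg(multiclass)
  if (is.null(seed)) seed <- cfg$seed
  t_start <- proc.time()[["elapsed"]]
  timing <- c(features = 0, fit = 0, predict = 0)
  ds <- as_dataset(x, labels, grid = grid, rmap = rmap, families = families,
                   norm_pool = norm_pool)
  y <- ds$labels
  classes <- sort(unique(y))
  abort_if(length(classes) < 2, "need >= 2 classes")
  check_min_trials(y, max(min_trials, outer_folds))
  n <- length(y)
  k_class <- length(classes)
  folds <- stratified_folds(y, outer_folds, derive_seed(seed, "outer"))
  fold_acc <- numeric(outer_folds)
  fold_logs <- vector("list", outer_folds)
  for (f in seq_len(outer_folds)) {
    tr <- which(folds != f); te <- which(folds == f)
    t0 <- proc.time()[["elapsed"]]
    ff <- fold_features(ds, tr)
    timing["features"] <- timing["features"] + proc.time()[["elapsed"]] - t0
    t0 <- proc.time()[["elapsed"]]
    if (k_class == 2) {
      fit <- fit_binary_pipeline(ff$X, y, tr, cfg,
                                 seed = derive_seed(seed, paste0("fold", f)),
                                 csp_augment = ff$csp_augment)
      timing["fit"] <- timing["fit"] + proc.time()[["elapsed"]] - t0
      t0 <- proc.time()[["elapsed"]]
      pred <- predict_binary_pipeline(
        fit, if (is.null(ff$X)) NULL else ff$X[te, , drop = FALSE], rows = te)
      fold_logs[[f]] <- list(selection = fit$selection,
                             smote = fit$smote_log)
      fold_acc[f] <- balanced_accuracy(y[te], pred$labels)
    } else if (multiclass == "voting") {
      cfg_f <- cfg; cfg_f$seed <- derive_seed(seed, paste0("fold", f))
      vm <- one_vs_rest_voting(ff$X, y, cfg_f, train_idx = tr,
                               min_trials = min_trials,
                               csp_augment = ff$csp_augment)
      timing["fit"] <- timing["fit"] + proc.time()[["elapsed"]] - t0
      t0 <- proc.time()[["elapsed"]]
      pred <- predict(vm, if (is.null(ff$X)) NULL else ff$X[te, , drop = FALSE],
                      rows = te)
      fold_logs[[f]] <- list(selection = lapply(vm$fits, `[[`, "selection"))
      fold_acc[f] <- balanced_accuracy(y[te], pred$labels)
    } else {
      cfg_f <- cfg; cfg_f$seed <- derive_seed(seed, paste0("fold", f))
      tree <- build_decision_tree(ff$X, y, cfg_f, train_idx = tr,
                                  min_trials = min_trials,
                                  csp_augment = ff$csp_augment)
      timing["fit"] <- timing["fit"] + proc.time()[["elapsed"]] - t0
      t0 <- proc.time()[["elapsed"]]
      lab <- predict_tree(tree, if (is.null(ff$X)) NULL
                          else ff$X[te, , drop = FALSE], rows = te)
      fold_logs[[f]] <- list()
      fold_acc[f] <- balanced_accuracy(y[te], lab)
    }
    timing["predict"] <- timing["predict"] + proc.time()[["elapsed"]] - t0
  }
  total <- proc.time()[["elapsed"]] - t_start
  structure(list(
    fold_balanced_accuracy = fold_acc,
    mean_balanced_accuracy = mean(fold_acc),
    n_trials = n, n_classes = k_class, outer_folds = outer_folds,
    multiclass = if (k_class > 2) multiclass else "binary",
    seed = seed,
    leaky_normalization = (ds$kind == "bandpower" && ds$norm_pool == "all"),
    runtime = c(timing, total = total),
    seconds_per_trial = total / n,
    fold_logs = fold_logs,
    config = cfg), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d-class, %d trials, %d-fold CV\n",
              x$n_classes, x$n_trials, x$outer_folds))
  cat(sprintf("  balanced accuracy: %.3f (folds: %s)\n",
              x$mean_balanced_accuracy,
              paste(sprintf("%.3f", x$fold_balanced_accuracy), collapse = " ")))
  if (!is.null(x$chance_level)) {
    cat(sprintf("  empirical chance level (p%g, %d perms): %.3f\n",
                x$chance_percentile, x$n_perm, x$chance_level))
  }
  if (isTRUE(x$leaky_normalization)) {
    cat("  WARNING: whole-set normalization mode (leaky)\n")
  }
  cat(sprintf("  runtime: %.2f s (%.3f s/trial)\n",
              x$runtime[["total"]], x$seconds_per_trial))
  invisible(x)
}

#' Empirical chance level by label permutation
#'
#' Repeats [cross_validate_pipeline()] with permuted labels and returns
#' the requested percentile (default 95) of the null balanced-accuracy
#' distribution.
#'
#' @param x,cfg,... as in [cross_validate_pipeline()].
#' @param n_perm permutations (>= 20; default 100).
#' @param percentile percentile of the null (default 95).
#' @param seed permutation seed.
#' @return list with `chance_level`, the `null` vector, `percentile`,
#'   `n_perm`, `seed`.
#' @export
permutation_chance_level <- function(x, cfg = pipeline_config(),
                                     n_perm = 100, percentile = 95,
                                     seed = 0, labels = NULL, ...) {
  abort_if(n_perm < 20, "need n_perm >= 20")
  ds <- as_dataset(x, labels)
  y <- ds$labels
  null <- vapply(seq_len(n_perm), function(i) {
    y_perm <- with_seed(derive_seed(seed, paste0("perm", i)), sample(y))
    rep <- cross_validate_pipeline(x, cfg, labels = y_perm,
                                   seed = derive_seed(seed, paste0("cv", i)),
                                   ...)
    rep$mean_balanced_accuracy
  }, numeric(1))
  list(chance_level = as.numeric(stats::quantile(null, percentile / 100)),
       null = null, percentile = percentile, n_perm = n_perm, seed = seed)
}

#' Seconds-per-trial runtime table of a report
#' @param report an `evaluation_report` (or list of them).
#' @return data frame with one row per stage.
#' @export
runtime_profile <- function(report) {
  reports <- if (inherits(report, "evaluation_report")) list(report) else report
  do.call(rbind, lapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    data.frame(run = i, stage = names(r$runtime),
               seconds = as.numeric(r$runtime),
               seconds_per_trial = as.numeric(r$runtime) / r$n_trials)
  }))
}
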