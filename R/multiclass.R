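# Multiclass generalization of the binary pipeline: one-vs-rest score
# voting and the optimal-partition binary decision tree.

#' Pipeline configuration for binary subproblems
#'
#' Bundles the per-subproblem processing shared by the evaluation and
#' multiclass modules: feature selection, SMOTE balancing, and the
#' classifier.
#'
#' @param selection `"filter+wrapper"` (default), `"filter"`, or
#'   `"none"`.
#' @param n_filter,n_select filter pool and final subset sizes
#'   (defaults 100 and 10).
#' @param balance apply SMOTE to the training split (default TRUE).
#' @param k_neighbors SMOTE neighbors (default 5).
#' @param balance_first SMOTE before selection instead of after
#'   (default FALSE: selection sees only original trials).
#' @param classifier a [classifier_spec()].
#' @param sfs_cv_folds folds of the SFS criterion (default 5).
#' @param seed base seed for every stochastic step.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(selection = "filter+wrapper",
                            n_filter = 100, n_select = 10,
                            balance = TRUE, k_neighbors = 5,
                            balance_first = FALSE,
                            classifier = classifier_spec("naive_bayes"),
                            sfs_cv_folds = 5, seed = 0) {
  structure(list(selection = selection, n_filter = n_filter,
                 n_select = n_select, balance = balance,
                 k_neighbors = k_neighbors, balance_first = balance_first,
                 classifier = classifier, sfs_cv_folds = sfs_cv_folds,
                 seed = seed),
            class = "pipeline_config")
}

# Fit the full binary pipeline (selection -> SMOTE -> classifier) on the
# given training rows. `csp_augment`, when supplied, appends binary-
# label-dependent CSP columns (fitted on the training rows only).
fit_binary_pipeline <- function(X, labels, train_idx, cfg, seed = cfg$seed,
                                csp_augment = NULL) {
  X_full <- NULL
  if (!is.null(csp_augment)) {
    X <- cbind(X, csp_augment(labels, train_idx))
    X_full <- X        # label-dependent columns: keep for row-indexed predict
  }
  Xtr <- X[train_idx, , drop = FALSE]
  ytr <- labels[train_idx]
  smote_log <- NULL
  if (cfg$balance && cfg$balance_first) {
    sm <- smote_oversample(Xtr, ytr, cfg$k_neighbors,
                           derive_seed(seed, "smote"))
    Xtr <- sm$X; ytr <- sm$labels; smote_log <- sm$log
  }
  sel <- select_features(Xtr, ytr, cfg$selection, cfg$n_filter, cfg$n_select,
                         cfg$classifier, cfg$sfs_cv_folds,
                         derive_seed(seed, "select"),
                         balance = cfg$balance && !cfg$balance_first,
                         k_neighbors = cfg$k_neighbors)
  Xs <- Xtr[, sel$selected, drop = FALSE]
  if (cfg$balance && !cfg$balance_first) {
    sm <- smote_oversample(Xs, ytr, cfg$k_neighbors,
                           derive_seed(seed, "smote"))
    Xs <- sm$X; ytr <- sm$labels; smote_log <- sm$log
  }
  model <- train_classifier(cfg$classifier, Xs, ytr,
                            seed = derive_seed(seed, "clf"))
  list(model = model, selection = sel, smote_log = smote_log,
       n_features_in = ncol(X), X_full = X_full)
}

# `rows` addresses the stored augmented matrix when the fit carries
# label-dependent (CSP) columns; otherwise X is used directly.
predict_binary_pipeline <- function(fit, X, rows = NULL) {
  if (!is.null(fit$X_full)) {
    abort_if(is.null(rows),
             "fit has label-dependent columns; predict needs row indices")
    X <- fit$X_full[rows, , drop = FALSE]
  }
  predict(fit$model, X[, fit$selection$selected, drop = FALSE])
}

check_min_trials <- function(labels, min_trials) {
  cnt <- table(labels)
  low <- names(cnt)[cnt < min_trials]
  abort_if(length(low) > 0,
           "class(es) below the %d-trial minimum: %s", min_trials,
           paste(sprintf("%s (n=%d)", low, cnt[low]), collapse = ", "))
}

#' One-vs-rest voting multiclass model
#'
#' Trains k binary subproblems (each class against the merged rest),
#' each with its own feature selection and SMOTE on its training rows.
#' A test trial receives one score per subproblem, oriented so larger
#' means more like the singleton class; the final label is the class
#' with the highest score.
#'
#' @param X trials x features matrix.
#' @param labels k >= 3 classes, each with at least `min_trials` trials.
#' @param cfg a [pipeline_config()].
#' @param train_idx training rows (default: all).
#' @param min_trials per-class minimum (default 20).
#' @param csp_augment optional `function(labels_bin, train_idx)`
#'   returning extra label-dependent columns (per-subproblem CSP).
#' @return a `voting_model`.
#' @export
one_vs_rest_voting <- function(X, labels, cfg = pipeline_config(),
                               train_idx = seq_len(nrow(X)),
                               min_trials = 20, csp_augment = NULL) {
  classes <- sort(unique(labels[train_idx]))
  abort_if(length(classes) < 3, "voting needs k >= 3 classes (got %d)",
           length(classes))
  check_min_trials(labels[train_idx], min_trials)
  fits <- lapply(seq_along(classes), function(ci) {
    labels_bin <- as.integer(labels == classes[ci])   # positive = singleton
    fit_binary_pipeline(X, labels_bin, train_idx, cfg,
                        seed = derive_seed(cfg$seed, paste0("ovr", ci)),
                        csp_augment = csp_augment)
  })
  structure(list(classes = classes, fits = fits, cfg = cfg,
                 csp_augment = csp_augment),
            class = "voting_model")
}

#' Predict from a one-vs-rest voting model
#' @param object a `voting_model`.
#' @param X trials x features matrix.
#' @param rows original row indices (required when the model was built
#'   with per-subproblem CSP augmentation).
#' @param ... unused.
#' @return list with `labels` (argmax class) and the `scores` matrix
#'   (one column per class).
#' @export
predict.voting_model <- function(object, X, rows = NULL, ...) {
  scores <- vapply(seq_along(object$classes), function(ci) {
    predict_binary_pipeline(object$fits[[ci]], X, rows = rows)$scores
  }, numeric(nrow(X)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = nrow(X))
  labels <- object$classes[max.col(scores, ties.method = "first")]
  list(labels = labels, scores = scores)
}

# All unordered 2-partitions of a class set: left part always contains
# the smallest class, masks enumerated in ascending order so the first
# maximum realizes the smallest-minimum-index tie rule.
two_partitions <- function(classes) {
  k <- length(classes)
  rest <- classes[-1]
  out <- list()
  for (mask in 0:(2^(k - 1) - 1)) {
    left <- c(classes[1], rest[bitwAnd(mask, 2^(seq_len(k - 1) - 1)) > 0])
    right <- setdiff(classes, left)
    if (length(right) == 0) next
    out[[length(out) + 1]] <- list(left = left, right = right)
  }
  out
}

#' Build the optimal-partition binary decision tree
#'
#' At every node holding class subset S, all `2^(|S|-1) - 1` unordered
#' 2-partitions are enumerated; for each, the full binary pipeline is
#' trained and scored by stratified cross-validated balanced accuracy on
#' the node's training trials, and the best partition is kept (ties to
#' the partition whose left set has the smallest minimum class index).
#' The node's final model is refitted on all node training trials, and
#' the children recurse until singleton leaves.
#'
#' @inheritParams one_vs_rest_voting
#' @param cv_folds partition-scoring folds (default 5).
#' @return a `partition_tree`.
#' @export
build_decision_tree <- function(X, labels, cfg = pipeline_config(),
                                train_idx = seq_len(nrow(X)),
                                cv_folds = 5, min_trials = 20,
                                csp_augment = NULL) {
  classes <- sort(unique(labels[train_idx]))
  check_min_trials(labels[train_idx], min_trials)
  root <- build_tree_node(X, labels, train_idx, classes, cfg, cv_folds,
                          derive_seed(cfg$seed, "tree"), csp_augment)
  structure(list(root = root, classes = classes, cfg = cfg),
            class = "partition_tree")
}

build_tree_node <- function(X, labels, node_idx, classes, cfg, cv_folds,
                            seed, csp_augment) {
  if (length(classes) == 1) {
    return(list(leaf = TRUE, class = classes))
  }
  parts <- two_partitions(classes)
  score_part <- function(part) {
    labels_bin <- as.integer(labels %in% part$left)
    cnt <- table(labels_bin[node_idx])
    abort_if(length(cnt) < 2 || any(cnt < cv_folds),
             "node class group below %d-fold CV feasibility", cv_folds)
    folds <- stratified_folds(labels_bin[node_idx], cv_folds,
                              derive_seed(seed, "part-folds"))
    accs <- numeric(cv_folds)
    for (f in seq_len(cv_folds)) {
      tr <- node_idx[folds != f]
      te <- node_idx[folds == f]
      fit <- fit_binary_pipeline(X, labels_bin, tr, cfg,
                                 seed = derive_seed(seed, "part-fit"),
                                 csp_augment = csp_augment)
      pred <- predict_binary_pipeline(fit, X[te, , drop = FALSE], rows = te)
      accs[f] <- balanced_accuracy(labels_bin[te], pred$labels)
    }
    mean(accs)
  }
  crit <- vapply(parts, score_part, numeric(1))
  best <- parts[[which.max(crit)]]
  labels_bin <- as.integer(labels %in% best$left)
  fit <- fit_binary_pipeline(X, labels_bin, node_idx, cfg,
                             seed = derive_seed(seed, "node-fit"),
                             csp_augment = csp_augment)
  left_idx <- node_idx[labels[node_idx] %in% best$left]
  right_idx <- node_idx[labels[node_idx] %in% best$right]
  list(leaf = FALSE, left_classes = best$left, right_classes = best$right,
       fit = fit, criterion = crit[which.max(crit)],
       candidates = data.frame(
         partition = vapply(parts, function(p)
           paste(p$left, collapse = "+"), ""),
         criterion = crit),
       left = build_tree_node(X, labels, left_idx, best$left, cfg, cv_folds,
                              derive_seed(seed, "L"), csp_augment),
       right = build_tree_node(X, labels, right_idx, best$right, cfg,
                               cv_folds, derive_seed(seed, "R"), csp_augment))
}

#' Route trials through a partition tree
#'
#' Each trial descends from the root by the node's binary decision
#' (positive score = left subset) until a singleton leaf; the label is
#' the leaf class.
#'
#' @param tree a `partition_tree`.
#' @param X trials x features matrix.
#' @param rows original row indices (required with per-subproblem CSP
#'   augmentation).
#' @return integer labels.
#' @export
predict_tree <- function(tree, X, rows = NULL) {
  out <- integer(nrow(X))
  route <- function(node, idx) {
    if (length(idx) == 0) return()
    if (node$leaf) { out[idx] <<- node$class; return() }
    pred <- predict_binary_pipeline(node$fit, X[idx, , drop = FALSE],
                                    rows = rows[idx])
    go_left <- pred$labels == 1   # positive class codes membership of left
    route(node$left, idx[go_left])
    route(node$right, idx[!go_left])
  }
  route(tree$root, seq_len(nrow(X)))
  out
}

#' Serialize a partition tree to nested JSON
#' @param tree a `partition_tree`.
#' @param path output file.
#' @export
write_tree <- function(tree, path) {
  strip <- function(node) {
    if (node$leaf) return(list(leaf = TRUE, class = node$class))
    list(leaf = FALSE,
         left_classes = node$left_classes,
         right_classes = node$right_classes,
         criterion = node$criterion,
         model_kind = node$fit$model$kind,
         selected = node$fit$selection$selected,
         left = strip(node$left), right = strip(node$right))
  }
  jsonlite::write_json(strip(tree$root), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
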