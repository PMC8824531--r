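# Feature selection: Fisher-score filter, sequential forward selection
# with a cross-validated criterion, and their combination.

#' Fisher separability scores per feature column
#'
#' For two classes the score of feature f is
#' `((mu1 - mu)^2 + (mu2 - mu)^2) / (s1^2 + s2^2)` with class sample
#' means/variances (denominator n-1) and grand mean `mu`. With more than
#' two classes the sum-over-classes generalization
#' `sum_c (mu_c - mu)^2 / sum_c s_c^2` is used, which reduces to the
#' two-class form at k = 2. Zero pooled variance gives score 0 with a
#' warning (a constant column separates nothing).
#'
#' @param X trials x features matrix.
#' @param labels per-trial classes (>= 2 distinct, each with >= 2 trials).
#' @return numeric score per column.
#' @export
fisher_scores <- function(X, labels) {
  classes <- sort(unique(labels))
  abort_if(length(classes) < 2, "need >= 2 classes")
  cnt <- table(factor(labels, classes))
  abort_if(any(cnt < 2), "every class needs >= 2 trials")
  mu <- colMeans(X)
  num <- 0; den <- 0
  for (cl in classes) {
    sub <- X[labels == cl, , drop = FALSE]
    num <- num + (colMeans(sub) - mu)^2
    den <- den + apply(sub, 2, stats::var)
  }
  s <- ifelse(den > 0, num / den, 0)
  if (any(den == 0)) {
    warning("zero-variance feature(s); Fisher score set to 0", call. = FALSE)
  }
  unname(s)
}

#' Select the k highest-scoring features
#'
#' Ties are broken toward the lower column index.
#'
#' @param scores per-column scores ([fisher_scores()]).
#' @param k number to keep (`1 <= k <= length(scores)`).
#' @return a `selection_result` with `method = "filter"`.
#' @export
filter_select <- function(scores, k) {
  abort_if(k <= 0, "k must be positive")
  abort_if(k > length(scores), "k exceeds the feature count")
  ord <- order(-scores, seq_along(scores))
  selection_result(ord[seq_len(k)], method = "filter",
                   pool_size = length(scores), target_size = k)
}

selection_result <- function(selected, method, pool_size, target_size,
                             criterion_trace = NULL, seed = NULL) {
  structure(list(selected = as.integer(selected), method = method,
                 pool_size = as.integer(pool_size),
                 target_size = as.integer(target_size),
                 criterion_trace = criterion_trace, seed = seed),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s: %d of %d features\n",
              x$method, length(x$selected), x$pool_size))
  invisible(x)
}

# Mean CV balanced accuracy of `spec` on the given columns, with a fixed
# fold assignment (paired across candidate subsets). When `balance` is
# TRUE the fold-training split is SMOTE-balanced first, so the criterion
# evaluates the same classifier the pipeline will finally train.
cv_criterion <- function(X, labels, cols, spec, folds, balance = FALSE,
                         k_neighbors = 5, seed = 0) {
  k <- max(folds)
  accs <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    abort_if(length(unique(labels[tr])) < 2,
             "degenerate CV fold: a class is absent from a training fold")
    Xtr <- X[tr, cols, drop = FALSE]
    ytr <- labels[tr]
    if (balance) {
      sm <- smote_oversample(Xtr, ytr, k_neighbors,
                             derive_seed(seed, paste0("crit-smote", f)))
      Xtr <- sm$X; ytr <- sm$labels
    }
    model <- train_classifier(spec, Xtr, ytr)
    pred <- predict(model, X[!tr, cols, drop = FALSE])
    accs[f] <- balanced_accuracy(labels[!tr], pred$labels)
  }
  mean(accs)
}

#' Sequential forward selection with a cross-validated criterion
#'
#' Greedy wrapper: starting from the empty set, repeatedly add the pool
#' feature whose addition maximizes the mean stratified-CV balanced
#' accuracy of the specified classifier. The fold assignment is fixed
#' once per run (seeded), so candidate comparisons are paired. Ties go
#' to the lower column index.
#'
#' @param X trials x features matrix.
#' @param labels per-trial classes.
#' @param pool candidate column indices (default: all).
#' @param target_size features to select.
#' @param spec classifier specification ([classifier_spec()]); also the
#'   default criterion classifier.
#' @param cv_folds criterion folds (default 5, stratified).
#' @param seed fold-assignment seed.
#' @param balance SMOTE-balance the criterion's fold-training splits so
#'   the criterion mirrors the finally trained classifier (default
#'   FALSE; the pipeline sets it to its own balancing switch).
#' @param k_neighbors SMOTE neighbors for `balance`.
#' @return a `selection_result` with the ordered `selected` indices and
#'   the `criterion_trace` (criterion after each addition).
#' @export
sfs_select <- function(X, labels, pool = seq_len(ncol(X)), target_size,
                       spec = classifier_spec("naive_bayes"),
                       cv_folds = 5, seed = 0, balance = FALSE,
                       k_neighbors = 5) {
  abort_if(target_size > length(pool), "target_size exceeds the pool")
  cnt <- table(labels)
  abort_if(any(cnt < cv_folds),
           "class with %d trials cannot support %d-fold CV", min(cnt), cv_folds)
  folds <- stratified_folds(labels, cv_folds, derive_seed(seed, "sfs-folds"))
  selected <- integer(0)
  trace <- numeric(0)
  remaining <- pool
  while (length(selected) < target_size) {
    crit <- vapply(remaining, function(j) {
      cv_criterion(X, labels, c(selected, j), spec, folds,
                   balance = balance, k_neighbors = k_neighbors,
                   seed = seed)
    }, numeric(1))
    best <- min(remaining[crit == max(crit)])   # ties -> lower column index
    selected <- c(selected, best)
    trace <- c(trace, max(crit))
    remaining <- setdiff(remaining, best)
  }
  selection_result(selected, method = "sfs", pool_size = length(pool),
                   target_size = target_size, criterion_trace = trace,
                   seed = seed)
}

#' Combined Fisher filter and SFS wrapper
#'
#' Keeps the `n_filter` features with the highest Fisher scores, then
#' runs [sfs_select()] on that pool for `n_select` features (defaults
#' 100 and 10). The wrapper sees only the filtered column indices and
#' values.
#'
#' @inheritParams sfs_select
#' @param n_filter filter pool size (default 100).
#' @param n_select final subset size (default 10).
#' @return a `selection_result` with `method = "filter+wrapper"`.
#' @export
filter_wrapper_select <- function(X, labels, n_filter = 100, n_select = 10,
                                  spec = classifier_spec("naive_bayes"),
                                  cv_folds = 5, seed = 0, balance = FALSE,
                                  k_neighbors = 5) {
  abort_if(n_select > n_filter, "n_select must be <= n_filter")
  n_filter <- min(n_filter, ncol(X))
  n_select <- min(n_select, n_filter)
  flt <- filter_select(fisher_scores(X, labels), n_filter)
  if (n_select == n_filter) {
    res <- flt
  } else {
    res <- sfs_select(X, labels, pool = flt$selected, target_size = n_select,
                      spec = spec, cv_folds = cv_folds, seed = seed,
                      balance = balance, k_neighbors = k_neighbors)
  }
  res$method <- "filter+wrapper"
  res$pool_size <- ncol(X)
  res
}

#' Run the configured selection method
#'
#' Dispatch helper used by the evaluation pipeline: `"none"` keeps all
#' columns, `"filter"` keeps the top-`n_select` by Fisher score, and
#' `"filter+wrapper"` runs the combination.
#'
#' @param X,labels data.
#' @param method one of `"none"`, `"filter"`, `"filter+wrapper"`.
#' @param n_filter,n_select pool and subset sizes.
#' @param spec,cv_folds,seed wrapper parameters.
#' @return a `selection_result`.
#' @export
select_features <- function(X, labels,
                            method = c("filter+wrapper", "filter", "none"),
                            n_filter = 100, n_select = 10,
                            spec = classifier_spec("naive_bayes"),
                            cv_folds = 5, seed = 0, balance = FALSE,
                            k_neighbors = 5) {
  method <- match.arg(method)
  if (method == "none") {
    return(selection_result(seq_len(ncol(X)), "none", ncol(X), ncol(X)))
  }
  if (method == "filter") {
    return(filter_select(fisher_scores(X, labels), min(n_select, ncol(X))))
  }
  filter_wrapper_select(X, labels, n_filter, n_select, spec, cv_folds, seed,
                        balance = balance, k_neighbors = k_neighbors)
}

#' Serialize a selection result to JSON
#' @param res a `selection_result`.
#' @param path output file.
#' @export
write_selection <- function(res, path) {
  jsonlite::write_json(
    list(method = res$method, selected = res$selected,
         criterion_trace = res$criterion_trace,
         pool_size = res$pool_size, target_size = res$target_size,
         seed = res$seed),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
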