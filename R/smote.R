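# SMOTE oversampling: every non-majority class is grown to the majority
# count by interpolating between a minority trial and one of its nearest
# minority neighbors. Applied to training data only.

#' SMOTE oversampling to class balance
#'
#' For each synthetic trial a minority trial `x` is taken (round-robin
#' over the minority trials in a seed-fixed random order), one of its
#' `k_neighbors` nearest minority neighbors `x'` (Euclidean) is picked
#' uniformly, and `x + u * (x' - x)` with `u ~ Uniform(0, 1)` is
#' emitted. After augmentation every class has the majority count.
#'
#' @param X trials x features matrix (training split only).
#' @param labels per-trial classes.
#' @param k_neighbors nearest-neighbor count (default 5; clamped to
#'   minority size - 1 with a warning when too large).
#' @param seed RNG seed.
#' @return list with the augmented `X`, `labels`, and `synthetic`
#'   (logical flag per row; FALSE for the original rows, which come
#'   first), plus a per-class augmentation `log`.
#' @export
smote_oversample <- function(X, labels, k_neighbors = 5, seed = 0) {
  abort_if(k_neighbors < 1, "k_neighbors must be >= 1")
  classes <- sort(unique(labels))
  cnt <- table(factor(labels, classes))
  n_max <- max(cnt)
  new_X <- list(); new_y <- integer(0)
  aug_log <- data.frame(class = as.integer(classes),
                        before = as.integer(cnt),
                        added = 0L)
  with_seed(derive_seed(seed, "smote"), {
    for (ci in seq_along(classes)) {
      cl <- classes[ci]
      need <- n_max - cnt[[ci]]
      if (need == 0) next
      idx <- which(labels == cl)
      abort_if(length(idx) < 2,
               "minority class %d has a single trial; SMOTE needs >= 2", cl)
      k <- k_neighbors
      if (k >= length(idx)) {
        k <- length(idx) - 1L
        warning(sprintf("k_neighbors clamped to %d for class %d", k, cl),
                call. = FALSE)
      }
      M <- X[idx, , drop = FALSE]
      D <- as.matrix(stats::dist(M))
      diag(D) <- Inf
      ord_nn <- apply(D, 1, function(r) order(r)[seq_len(k)])
      nn <- if (k == 1) matrix(ord_nn, ncol = 1) else t(ord_nn)
      ord <- sample.int(length(idx))             # round-robin order
      base <- ord[((seq_len(need) - 1L) %% length(idx)) + 1L]
      pick <- if (k == 1) rep(1L, need) else sample.int(k, need, replace = TRUE)
      u <- stats::runif(need)
      nb <- nn[cbind(base, pick)]
      synth <- M[base, , drop = FALSE] +
        u * (M[nb, , drop = FALSE] - M[base, , drop = FALSE])
      new_X[[length(new_X) + 1]] <- synth
      new_y <- c(new_y, rep(cl, need))
      aug_log$added[ci] <- as.integer(need)
    }
  })
  if (length(new_X) == 0) {
    return(list(X = X, labels = labels,
                synthetic = rep(FALSE, nrow(X)), log = aug_log))
  }
  Xa <- rbind(X, do.call(rbind, new_X))
  list(X = Xa, labels = c(labels, new_y),
       synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, nrow(Xa) - nrow(X))),
       log = aug_log)
}
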