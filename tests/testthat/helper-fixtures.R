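# Shared fixtures, built in code at test time.

# 16-channel montage covering all four regions (4 channels each).
montage16 <- function() {
  c("AF3", "F3", "F7", "FC5",      # frontal-left
    "AF4", "F4", "F8", "FC6",      # frontal-right
    "P3", "P7", "PO3", "O1",       # posterior-left
    "P4", "P8", "PO4", "O2")       # posterior-right
}

# 8-channel montage, 2 per region (cheap pipelines).
montage8 <- function() {
  c("F3", "F7", "F4", "F8", "P3", "O1", "P4", "O2")
}

# Hand-built band_power object with full control over the values.
# bp: trials x channels x bands x time array.
fake_band_power <- function(bp, fs_out = 50, t_start_ms = 0,
                            channel_names = NULL, labels = NULL,
                            band_names = NULL, normalized = TRUE) {
  d <- dim(bp)
  if (is.null(channel_names)) channel_names <- sprintf("ch%02d", seq_len(d[2]))
  if (is.null(band_names)) band_names <- paste0("b", seq_len(d[3]))
  if (is.null(labels)) labels <- rep(1:2, length.out = d[1])
  bands <- stats::setNames(lapply(seq_len(d[3]), function(i) c(i, i)),
                           band_names)
  structure(list(bp = bp, bands = bands, band_names = band_names,
                 times_ms = t_start_ms + (seq_len(d[4]) - 0.5) / fs_out * 1000,
                 fs_out = fs_out, channel_names = channel_names,
                 labels = labels, normalized = normalized,
                 norm_stats = NULL),
            class = "band_power")
}

# region map with one channel per region (passthrough averaging)
rmap4 <- function(chs = c("FL", "FR", "PL", "PR")) {
  region_map(stats::setNames(
    c("frontal-left", "frontal-right", "posterior-left", "posterior-right"),
    chs))
}

# Two-class Gaussian feature matrix with `n_informative` shifted columns.
gaussian_features <- function(n_per_class = 30, p = 20, delta = 2,
                              n_informative = 3, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  X <- matrix(rnorm(n * p), n, p)
  labels <- rep(1:2, each = n_per_class)
  X[labels == 2, seq_len(n_informative)] <-
    X[labels == 2, seq_len(n_informative)] + delta
  list(X = X, labels = labels)
}

# Small synthetic epoch world used by pipeline-level tests: 8 channels,
# 0-800 ms analysis interval (3 windows), alpha amplitude effect on the
# posterior channels.
small_world <- function(n1 = 30, n2 = 30, amp_mult = 2, seed = 1,
                        effects = NULL) {
  if (is.null(effects)) {
    effects <- list(list(class = 2L, oscillation = "alpha",
                         channels = c("P3", "O1", "P4", "O2"),
                         window_ms = c(0, 800), amp_mult = amp_mult))
  }
  synthetic_spec(
    n_trials = c(`1` = n1, `2` = n2), channels = montage8(),
    fs = 256, epoch_ms = c(-800, 1600),
    effects = effects, seed = seed)
}

small_grid <- function() make_window_grid(0, 800, 400, 200)

# Band power of a generated small world (raw, unnormalized).
small_band_power <- function(spec) {
  gen <- generate_epochs(spec)
  tfr <- morlet_transform(gen$epochs, crop_ms = c(0, 800))
  list(bpw = aggregate_band_power(tfr), truth = gen$truth,
       epochs = gen$epochs)
}

# Independent small-QP oracle for the SVM dual: enumerate active sets
# over {lower bound, upper bound, free}, solve the KKT system for the
# free block, keep the feasible solution with the best dual objective.
svm_dual_oracle <- function(X, y, C) {
  n <- nrow(X)
  Q <- tcrossprod(X) * tcrossprod(y)
  best <- NULL; best_obj <- Inf
  states <- expand.grid(rep(list(0:2), n))   # 0 = at 0, 1 = at C, 2 = free
  for (r in seq_len(nrow(states))) {
    st <- as.integer(states[r, ])
    alpha <- ifelse(st == 1, C, 0)
    free <- which(st == 2)
    fixed_contrib <- sum(y * alpha)
    if (length(free) > 0) {
      A <- rbind(cbind(Q[free, free, drop = FALSE], y[free]),
                 c(y[free], 0))
      rhs <- c(1 - (if (any(st == 1)) Q[free, st == 1, drop = FALSE] %*%
                      rep(C, sum(st == 1)) else 0),
               -fixed_contrib)
      sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      alpha[free] <- sol[seq_along(free)]
      if (any(alpha[free] < -1e-9 | alpha[free] > C + 1e-9)) next
    } else if (abs(fixed_contrib) > 1e-9) next
    obj <- 0.5 * t(alpha) %*% Q %*% alpha - sum(alpha)
    if (obj < best_obj - 1e-12) { best_obj <- obj; best <- alpha }
  }
  list(alpha = best, obj = as.numeric(best_obj))
}
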