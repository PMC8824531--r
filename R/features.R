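# Feature extraction: eight families per (window x band x channel/region)
# cell, assembled into a descriptor-indexed feature matrix.
#
# Families and their loci:
#   mean, variance, entropy, phase  -> per channel
#   correlation, phase_sync         -> per unordered region pair
#   ar                              -> per region (ar_order coefficients)
#   csp                             -> per projected component

#' The eight feature families, in canonical column order
#' @format character vector.
#' @export
FEATURE_FAMILIES <- c("mean", "variance", "entropy", "phase",
                      "correlation", "phase_sync", "ar", "csp")

region_pairs <- function() {
  p <- utils::combn(4, 2)
  data.frame(i = p[1, ], j = p[2, ],
             name = paste(REGION_NAMES[p[1, ]], REGION_NAMES[p[2, ]],
                          sep = "~"))
}

#' Closed-form feature-space dimensionality
#'
#' `4*B*W*C` (mean, variance, entropy, phase over channels) +
#' `2*B*W*P` (correlation, phase synchrony over region pairs) +
#' `p*B*W*R` (AR coefficients per region) + `B*W*K` (CSP components).
#' The default montage (C = 32, B = 4, W = 9, R = 4, p = 4, K = 32)
#' gives 6768.
#'
#' @param n_channels,n_bands,n_windows,n_regions montage/config sizes.
#' @param ar_order AR model order (default 4).
#' @param csp_components projected components kept (default `n_channels`).
#' @param families subset of feature families to count.
#' @return integer column count.
#' @export
feature_count <- function(n_channels = 32, n_bands = 4, n_windows = 9,
                          n_regions = 4, ar_order = 4,
                          csp_components = n_channels,
                          families = FEATURE_FAMILIES) {
  n_pairs <- choose(n_regions, 2)
  per <- c(mean = n_channels, variance = n_channels, entropy = n_channels,
           phase = n_channels, correlation = n_pairs, phase_sync = n_pairs,
           ar = ar_order * n_regions, csp = csp_components)
  sum(per[families]) * n_bands * n_windows
}

# Batched analytic-signal phase: input array trials x loci x bands x time,
# output same dims. Series are mean-centered before the transform.
analytic_phase_array <- function(bp) {
  d <- dim(bp)
  S <- d[4]
  m <- matrix(aperm(bp, c(4, 1, 2, 3)), nrow = S)
  m <- sweep(m, 2, colMeans(m))
  h <- numeric(S)
  if (S %% 2 == 0) { h[1] <- 1; h[S / 2 + 1] <- 1; h[2:(S / 2)] <- 2
  } else { h[1] <- 1; h[2:((S + 1) / 2)] <- 2 }
  A <- stats::mvfft(stats::mvfft(m) * h, inverse = TRUE) / S
  aperm(array(Arg(A), c(S, d[1], d[2], d[3])), c(2, 3, 4, 1))
}

# Row-wise sample variance of a trials x samples matrix.
rowvars <- function(m) {
  n <- ncol(m)
  (rowSums(m^2) - n * rowMeans(m)^2) / (n - 1)
}

# ---------------------------------------------------------------------------
# CSP

#' Fit common spatial pattern filters per (band, window) cell
#'
#' For each band and window, the per-trial channel covariance of the
#' in-window power series is averaged within each class (`C1bar`,
#' `C2bar`); the filters `W` jointly diagonalize `C1bar` and
#' `C1bar + C2bar`, ordered by decreasing generalized eigenvalue, so the
#' leading/trailing filters maximize the class-1/class-2 variance ratio.
#' Fitted on training trials only.
#'
#' Class covariances are stabilized by Ledoit-Wolf analytic shrinkage
#' toward the scaled identity (`shrinkage = NULL`, the default, computes
#' the intensity from the data; pass a number in `[0, 1]` to fix it, or
#' 0 to disable). Shrinkage is essential here: per-trial covariances
#' come from 20-sample windows, so unshrunk generalized eigenfilters
#' overfit the training split and their variance features acquire
#' spuriously inflated Fisher scores.
#'
#' @param bpw normalized channel-level `band_power`.
#' @param grid a [make_window_grid()] grid.
#' @param train_idx training trial indices.
#' @param labels per-trial class labels (exactly 2 classes among
#'   `train_idx`).
#' @param n_components filters kept (default: all channels).
#' @param shrinkage covariance shrinkage intensity (default: analytic).
#' @return a `csp_model`: list of per-cell `W`, `C1bar`, `C2bar`,
#'   eigenvalues, plus the class pair and grid.
#' @export
fit_csp <- function(bpw, grid, train_idx, labels, n_components = NULL,
                    shrinkage = NULL) {
  stopifnot(inherits(bpw, "band_power"), inherits(grid, "window_grid"))
  d <- dim(bpw$bp)
  C <- d[2]
  if (is.null(n_components)) n_components <- C
  classes <- sort(unique(labels[train_idx]))
  abort_if(length(classes) != 2, "CSP requires exactly 2 classes, got %d",
           length(classes))
  i1 <- train_idx[labels[train_idx] == classes[1]]
  i2 <- train_idx[labels[train_idx] == classes[2]]
  abort_if(length(i1) < 2 || length(i2) < 2,
           "CSP needs >= 2 training trials per class")
  win_idx <- window_samples(grid, bpw$times_ms)
  nb <- d[3]; nw <- length(win_idx)
  cells <- vector("list", nb * nw)
  # class covariance: mean of per-trial channel covariances, then
  # Ledoit-Wolf shrinkage toward (tr(S)/p) I computed from the pooled
  # per-trial-centered samples
  class_cov <- function(trials, b, idx) {
    n_s <- length(idx)
    rows <- do.call(rbind, lapply(trials, function(tr) {
      m <- matrix(bpw$bp[tr, , b, idx], nrow = C)
      t(m - rowMeans(m))                         # samples x channels
    }))
    S <- crossprod(rows) / (length(trials) * (n_s - 1))
    rho <- shrinkage
    if (is.null(rho)) {
      N <- nrow(rows)
      Sp <- crossprod(rows) / N
      mI <- sum(diag(Sp)) / C
      d2 <- sum((Sp - diag(mI, C))^2) / C
      b2 <- (sum(rowSums(rows^2)^2) / N - sum(Sp^2)) / (N * C)
      rho <- if (d2 > 0) min(1, max(0, b2 / d2)) else 0
    }
    (1 - rho) * S + rho * (sum(diag(S)) / C) * diag(C)
  }
  for (b in seq_len(nb)) for (w in seq_len(nw)) {
    idx <- win_idx[[w]]
    C1 <- class_cov(i1, b, idx)
    C2 <- class_cov(i2, b, idx)
    Cc <- C1 + C2
    ev <- eigen(Cc, symmetric = TRUE)
    if (min(ev$values) < 1e-10 * sum(diag(Cc))) {
      lam <- 1e-6 * sum(diag(Cc)) / C
      C1 <- C1 + diag(lam / 2, C); C2 <- C2 + diag(lam / 2, C)
      Cc <- C1 + C2
      ev <- eigen(Cc, symmetric = TRUE)
      log_msg("csp", "ridge-regularized singular covariance (band %d, window %d)",
              b, w)
    }
    P <- ev$vectors %*% diag(1 / sqrt(pmax(ev$values, 1e-300))) # whitener
    Sw <- crossprod(P, C1 %*% P)
    Sw <- (Sw + t(Sw)) / 2
    es <- eigen(Sw, symmetric = TRUE)               # values in [0, 1], desc
    W <- P %*% es$vectors
    keep <- if (n_components >= C) seq_len(C) else {
      # fewer than all: keep the extreme pairs (largest and smallest
      # generalized eigenvalues), the standard reduced-CSP practice
      k_hi <- ceiling(n_components / 2)
      k_lo <- n_components - k_hi
      c(seq_len(k_hi), if (k_lo > 0) (C - k_lo + 1):C)
    }
    cells[[(b - 1) * nw + w]] <- list(W = W[, keep, drop = FALSE],
                                      eig = es$values[keep],
                                      C1bar = C1, C2bar = C2)
  }
  structure(list(cells = cells, n_bands = nb, n_windows = nw,
                 classes = classes, n_components = min(n_components, C),
                 grid = grid, band_names = bpw$band_names),
            class = "csp_model")
}

#' Project band power through fitted CSP filters and take variances
#'
#' Per (band, window) cell the in-window multichannel power series is
#' projected through the cell's filters; the feature is the sample
#' variance of each projected series.
#'
#' @param bpw normalized channel-level `band_power`.
#' @param grid the window grid the model was fitted with.
#' @param model a [fit_csp()] model.
#' @return matrix `trials x (bands * windows * components)`.
#' @export
extract_csp_features <- function(bpw, grid, model) {
  stopifnot(inherits(model, "csp_model"))
  d <- dim(bpw$bp)
  win_idx <- window_samples(grid, bpw$times_ms)
  abort_if(model$n_windows != length(win_idx) || model$n_bands != d[3],
           "CSP model grid/band mismatch")
  K <- model$n_components
  nb <- d[3]; nw <- length(win_idx)
  out <- matrix(NA_real_, d[1], nb * nw * K)
  col <- 0
  for (b in seq_len(nb)) for (w in seq_len(nw)) {
    cell <- model$cells[[(b - 1) * nw + w]]
    idx <- win_idx[[w]]
    for (tr in seq_len(d[1])) {
      m <- matrix(bpw$bp[tr, , b, idx], nrow = d[2])  # channels x samples
      pr <- crossprod(cell$W, m)                      # K x samples
      out[tr, col + seq_len(K)] <- rowvars(pr)
    }
    col <- col + K
  }
  out
}

# ---------------------------------------------------------------------------
# Feature matrix assembly

#' Extract the feature matrix from band power
#'
#' Computes the requested feature families from an *unnormalized*
#' channel-level band power, handling normalization (training statistics
#' only, by default) and CSP fitting on the supplied training trials.
#' Column order is deterministic: family, band, window, locus,
#' coefficient.
#'
#' @param bpw_raw unnormalized channel-level `band_power`.
#' @param grid a [make_window_grid()] grid.
#' @param rmap a [region_map()] (required for regional families).
#' @param train_idx trial indices used to fit normalization statistics
#'   and CSP; defaults to all trials.
#' @param families feature families to include (default: all eight).
#' @param n_bins entropy histogram bins (default 5).
#' @param ar_order AR model order (default 4).
#' @param csp_components CSP filters kept (default: all channels).
#' @param norm_pool `"train"` (default, leakage-safe) or `"all"`
#'   (pools every trial, matching per-participant whole-set
#'   normalization).
#' @param csp_model optionally reuse a fitted [fit_csp()] model.
#' @param phases optional phase array `trials x channels x bands x time`
#'   (e.g. [band_phase_from_coefs()], the wavelet-native phase) used by
#'   the phase/phase-synchrony families instead of the Hilbert phase of
#'   the band-power series.
#' @param phase_stat `"mrl"` (mean resultant length, default) or
#'   `"angle"` (circular-mean angle) for the phase family.
#' @return a `feature_matrix`: `X` (trials x features), `descriptors`
#'   data frame (family, band, window, locus, coef), `labels`, and the
#'   fitted `csp_model`/`norm_stats`.
#' @export
extract_features <- function(bpw_raw, grid, rmap = NULL,
                             train_idx = NULL,
                             families = FEATURE_FAMILIES,
                             n_bins = 5, ar_order = 4,
                             csp_components = NULL,
                             norm_pool = c("train", "all"),
                             csp_model = NULL, phases = NULL,
                             phase_stat = c("mrl", "angle")) {
  stopifnot(inherits(bpw_raw, "band_power"), inherits(grid, "window_grid"))
  norm_pool <- match.arg(norm_pool)
  bad <- setdiff(families, FEATURE_FAMILIES)
  abort_if(length(bad) > 0, "unknown feature families: %s",
           paste(bad, collapse = ", "))
  d <- dim(bpw_raw$bp)
  n_tr <- d[1]
  if (is.null(train_idx)) train_idx <- seq_len(n_tr)
  labels <- bpw_raw$labels

  pool <- if (norm_pool == "train") train_idx else seq_len(n_tr)
  bpw <- if (bpw_raw$normalized) bpw_raw else normalize_band_power(bpw_raw, pool)

  win_idx <- window_samples(grid, bpw$times_ms)
  nb <- d[3]; nw <- length(win_idx)
  bands <- bpw$band_names

  need_regions <- any(c("correlation", "phase_sync", "ar") %in% families)
  if (need_regions) {
    abort_if(is.null(rmap), "regional families requested but no region map")
    rbp <- average_regions(bpw, rmap)
  }
  phase_stat <- match.arg(phase_stat)
  if (!is.null(phases)) {
    abort_if(!all(dim(phases) == d), "phase array dimension mismatch")
  }
  if ("phase" %in% families) {
    ph_ch <- if (is.null(phases)) analytic_phase_array(bpw$bp) else phases
  }
  if ("phase_sync" %in% families) {
    ph_rg <- if (is.null(phases)) analytic_phase_array(rbp$bp) else {
      # region phase = circular mean of member-channel phases
      idxr <- region_indices(rmap, bpw$channel_names)
      pr <- array(0, c(d[1], 4, d[3], d[4]))
      for (r in seq_along(REGION_NAMES)) {
        z <- exp(1i * phases[, idxr[[r]], , , drop = FALSE])
        pr[, r, , ] <- Arg(rowSums(aperm(z, c(1, 3, 4, 2)), dims = 3))
      }
      pr
    }
  }
  pairs <- region_pairs()

  blocks <- list(); descs <- list()
  add <- function(fam, X, band, window, locus, coef = NA_integer_) {
    blocks[[length(blocks) + 1]] <<- X
    descs[[length(descs) + 1]] <<- data.frame(
      family = fam, band = band, window = window,
      locus = locus, coef = coef, stringsAsFactors = FALSE)
  }
  warn_flags <- new.env()
  warn_once <- function(key, fmt, ...) {
    log_msg("features", fmt, ...)
    if (is.null(warn_flags[[key]])) {
      warn_flags[[key]] <- TRUE
      warning(sprintf(fmt, ...), call. = FALSE)
    }
  }

  for (fam in FEATURE_FAMILIES) {
    if (!fam %in% families) next
    if (fam == "csp") {
      if (is.null(csp_model)) {
        csp_model <- fit_csp(bpw, grid, train_idx, labels, csp_components)
      }
      Xc <- extract_csp_features(bpw, grid, csp_model)
      K <- csp_model$n_components
      col <- 0
      for (b in seq_len(nb)) for (w in seq_len(nw)) {
        add("csp", Xc[, col + seq_len(K), drop = FALSE], bands[b], w,
            sprintf("csp%02d", seq_len(K)))
        col <- col + K
      }
      next
    }
    for (b in seq_len(nb)) for (w in seq_len(nw)) {
      idx <- win_idx[[w]]
      if (fam %in% c("mean", "variance", "entropy", "phase")) {
        if (fam == "phase") {
          z <- exp(1i * ph_ch[, , b, idx, drop = FALSE])
          zm <- rowSums(z, dims = 2) / length(idx)
          val <- if (phase_stat == "mrl") Mod(zm) else Arg(zm)
          dim(val) <- c(n_tr, d[2])
        } else {
          cube <- bpw$bp[, , b, idx, drop = FALSE]
          dim(cube) <- c(n_tr, d[2], length(idx))
          val <- switch(fam,
            mean = rowMeans(cube, dims = 2),
            variance = {
              n <- length(idx)
              (rowSums(cube^2, dims = 2) - n * rowMeans(cube, dims = 2)^2) / (n - 1)
            },
            entropy = entropy_cells(cube, n_bins))
          dim(val) <- c(n_tr, d[2])
        }
        add(fam, val, bands[b], w, bpw$channel_names)
      } else if (fam == "correlation") {
        val <- matrix(NA_real_, n_tr, nrow(pairs))
        for (p in seq_len(nrow(pairs))) {
          x <- matrix(rbp$bp[, pairs$i[p], b, idx], n_tr)
          y <- matrix(rbp$bp[, pairs$j[p], b, idx], n_tr)
          xc <- x - rowMeans(x); yc <- y - rowMeans(y)
          den <- sqrt(rowSums(xc^2) * rowSums(yc^2))
          r <- ifelse(den > 0, rowSums(xc * yc) / den, 0)
          if (any(den == 0)) {
            warn_once("cor0", "zero-variance window in correlation; value set to 0")
          }
          val[, p] <- r
        }
        add(fam, val, bands[b], w, pairs$name)
      } else if (fam == "phase_sync") {
        val <- matrix(NA_real_, n_tr, nrow(pairs))
        for (p in seq_len(nrow(pairs))) {
          dphi <- ph_rg[, pairs$i[p], b, idx] - ph_rg[, pairs$j[p], b, idx]
          dim(dphi) <- c(n_tr, length(idx))
          val[, p] <- Mod(rowMeans(exp(1i * dphi)))
        }
        add(fam, val, bands[b], w, pairs$name)
      } else if (fam == "ar") {
        abort_if(length(idx) <= ar_order + 1,
                 "window has %d samples; AR(%d) needs > %d",
                 length(idx), ar_order, ar_order + 1)
        val <- matrix(NA_real_, n_tr, 4 * ar_order)
        for (r in seq_len(4)) {
          series <- matrix(rbp$bp[, r, b, idx], n_tr)
          for (tr in seq_len(n_tr)) {
            cf <- ar_ols(series[tr, ], ar_order)
            if (is.null(cf)) {
              cf <- rep(0, ar_order)
              warn_once("ar0", "rank-deficient AR regression; coefficients set to 0")
            }
            val[tr, (r - 1) * ar_order + seq_len(ar_order)] <- cf
          }
        }
        add(fam, val, bands[b], w,
            rep(REGION_NAMES, each = ar_order), rep(seq_len(ar_order), 4))
      }
    }
  }

  X <- do.call(cbind, blocks)
  descriptors <- do.call(rbind, descs)
  rownames(descriptors) <- NULL
  colnames(X) <- with(descriptors,
                      paste0(family, ".", band, ".w", window, ".", locus,
                             ifelse(is.na(coef), "", paste0(".a", coef))))
  abort_if(any(!is.finite(X)), "non-finite feature values produced")
  structure(list(X = X, descriptors = descriptors, labels = labels,
                 csp_model = csp_model, norm_stats = bpw$norm_stats,
                 grid = grid),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d trials x %d features (%s)\n",
              nrow(x$X), ncol(x$X),
              paste(unique(x$descriptors$family), collapse = ", ")))
  invisible(x)
}

# Shannon entropy (bits) of each (trial, channel) cell of a
# trials x channels x samples cube: equal-width histogram over the
# cell's own min-max range; all-equal cells have entropy 0.
entropy_cells <- function(cube, n_bins) {
  abort_if(n_bins < 2, "n_bins must be >= 2")
  d <- dim(cube)
  n_cells <- d[1] * d[2]
  m <- matrix(cube, n_cells, d[3])
  lo <- apply(m, 1, min); hi <- apply(m, 1, max)
  rng <- hi - lo
  flat <- (m - lo) / ifelse(rng > 0, rng, 1)
  bin <- pmin(floor(flat * n_bins) + 1L, n_bins)
  cell_id <- rep(seq_len(n_cells), times = d[3])
  counts <- matrix(tabulate((cell_id - 1L) * n_bins + as.integer(bin),
                            nbins = n_cells * n_bins), n_bins, n_cells)
  p <- counts / d[3]
  H <- -colSums(ifelse(p > 0, p * log2(p), 0))
  H[rng == 0] <- 0
  matrix(H, d[1], d[2])
}

# OLS fit of an AR(p) model on one series (conditional likelihood):
# x[n] = sum_i alpha_i x[n-i] + u[n]. Returns the p coefficients, or
# NULL when the lagged design is rank deficient.
ar_ols <- function(x, p) {
  emb <- stats::embed(x, p + 1)
  y <- emb[, 1]
  Xl <- emb[, -1, drop = FALSE]
  XtX <- crossprod(Xl)
  ok <- tryCatch({
    R <- chol(XtX)
    TRUE
  }, error = function(e) FALSE)
  if (!ok || rcond(XtX) < 1e-12) return(NULL)
  as.numeric(solve(XtX, crossprod(Xl, y)))
}

#' Full pipeline feature extraction from epochs
#'
#' Convenience wrapper: Morlet transform, band aggregation, normalization,
#' and [extract_features()] with the default configuration. For
#' cross-validated use prefer computing the band power once and calling
#' [extract_features()] per fold.
#'
#' @param ep an [epoch_set()].
#' @param grid window grid (default 0-2000 ms, 400/200).
#' @param rmap region map (default [default_region_map()] on the epoch's
#'   channels).
#' @param train_idx training trials for normalization/CSP (default all).
#' @param families,n_bins,ar_order,csp_components,norm_pool passed to
#'   [extract_features()].
#' @param bands,freqs,n_cycles,fs_out passed to the transform.
#' @return a `feature_matrix`.
#' @export
extract_all <- function(ep, grid = make_window_grid(),
                        rmap = default_region_map(ep$channel_names),
                        train_idx = NULL,
                        families = FEATURE_FAMILIES,
                        bands = default_bands(), freqs = default_freqs(),
                        n_cycles = 5, fs_out = 50.25,
                        n_bins = 5, ar_order = 4, csp_components = NULL,
                        norm_pool = "train") {
  crop <- c(min(grid$windows[, 1]), max(grid$windows[, 2]))
  tfr <- morlet_transform(ep, freqs, n_cycles, fs_out, crop_ms = crop)
  bpw <- aggregate_band_power(tfr, bands)
  extract_features(bpw, grid, rmap, train_idx, families,
                   n_bins, ar_order, csp_components, norm_pool)
}

#' Write a feature matrix as TSV (descriptor header + label column)
#' @param fm a `feature_matrix`.
#' @param path output file.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(label = fm$labels, fm$X, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#' @param path TSV file.
#' @return a `feature_matrix` (descriptors reconstructed from the header).
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  X <- as.matrix(df[, -1, drop = FALSE])
  parts <- strsplit(colnames(X), ".", fixed = TRUE)
  descriptors <- data.frame(
    family = vapply(parts, `[`, "", 1),
    band = vapply(parts, `[`, "", 2),
    window = as.integer(sub("^w", "", vapply(parts, `[`, "", 3))),
    locus = vapply(parts, `[`, "", 4),
    coef = vapply(parts, function(p)
      if (length(p) >= 5) as.integer(sub("^a", "", p[5])) else NA_integer_,
      1L))
  structure(list(X = X, descriptors = descriptors, labels = df$label,
                 csp_model = NULL, norm_stats = NULL, grid = NULL),
            class = "feature_matrix")
}
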