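# Time-frequency representation: complex Morlet transform, band-power
# aggregation, normalization, region averaging, and the analysis window grid.

#' Default frequency grid: 78 linearly spaced frequencies from 3 to 80 Hz
#' @return numeric vector of length 78 (spacing 1 Hz).
#' @export
default_freqs <- function() seq(3, 80, length.out = 78)

#' Default frequency bands (Hz, closed intervals on the grid)
#'
#' theta 3-7, alpha 8-12, beta 13-30, gamma 35-80. Grid lines between
#' bands (31-34 Hz) belong to no band.
#' @return named list of `c(lo, hi)` pairs.
#' @export
default_bands <- function() {
  list(theta = c(3, 7), alpha = c(8, 12), beta = c(13, 30), gamma = c(35, 80))
}

# Morlet kernel at frequency f: Gaussian envelope with sigma_t =
# n_cycles / (2*pi*f), L1-normalized envelope so a unit-amplitude sinusoid
# at f yields |coef| ~= 0.5. Support +-5 sigma.
morlet_kernel <- function(f, fs, n_cycles) {
  sigma <- n_cycles / (2 * pi * f)
  h <- ceiling(5 * sigma * fs)
  t <- (-h:h) / fs
  env <- exp(-t^2 / (2 * sigma^2))
  env <- env / sum(env)
  env * exp(2i * pi * f * t)
}

# Windowed-sinc resampling weights: rows = output instants (seconds,
# same origin as `t_in`), cols = input samples. Hann-windowed sinc at
# cutoff 0.45 * min(fs_in, fs_out); identity when grids coincide.
resample_weights <- function(t_in, t_out, fs_in, fs_out, taps = 33L) {
  if (fs_out >= fs_in) {
    # interpolation only: cubic-like windowed sinc at input Nyquist
    fc <- 0.5 * fs_in
  } else {
    fc <- 0.45 * fs_out
  }
  half_span <- (taps / 2) / fs_in
  W <- matrix(0, length(t_out), length(t_in))
  for (k in seq_along(t_out)) {
    dt <- t_out[k] - t_in
    sel <- which(abs(dt) <= half_span)
    u <- 2 * fc * dt[sel]
    s <- ifelse(u == 0, 1, sin(pi * u) / (pi * u))
    win <- 0.5 + 0.5 * cos(pi * dt[sel] / half_span)
    w <- s * win * (2 * fc / fs_in)
    W[k, sel] <- w / sum(w)           # unity DC gain
  }
  W
}

#' Morlet wavelet time-frequency transform
#'
#' Convolves every trial and channel with complex Morlet wavelets (default
#' 78 linearly spaced frequencies, 3-80 Hz, 5 cycles), takes squared
#' magnitudes, crops to the analysis interval, and resamples the power
#' series to `fs_out` (default 50.25 Hz). The resampled grid places
#' samples at half-step offsets (`t = start + (k + 0.5)/fs_out`), which at
#' 50.25 Hz puts exactly 20 samples in every 400-ms analysis window.
#'
#' The epoch must extend beyond the analysis interval so that
#' edge-affected samples are discarded (wavelet support is +-5 sigma,
#' sigma = n_cycles / (2 pi f)).
#'
#' @param ep an [epoch_set()].
#' @param freqs frequency grid in Hz, strictly increasing, inside
#'   `(0, fs/2)`.
#' @param n_cycles wavelet cycles (default 5).
#' @param fs_out output sampling rate, Hz (default 50.25); `NULL` keeps
#'   the native input grid (no resampling).
#' @param crop_ms analysis interval `c(start, end)` in ms relative to
#'   stimulus onset; default `c(0, 2000)`.
#' @param keep_phase keep resampled complex coefficients (for wavelet-
#'   native phase features); default FALSE.
#' @return a `tf_power` object: `power` array
#'   `trials x channels x frequencies x time`, `freqs_hz`, `fs_out`,
#'   `times_ms`, and optionally `coefs`.
#' @export
morlet_transform <- function(ep, freqs = default_freqs(), n_cycles = 5,
                             fs_out = 50.25, crop_ms = c(0, 2000),
                             keep_phase = FALSE) {
  stopifnot(inherits(ep, "epoch_set"))
  abort_if(any(freqs <= 0) || any(freqs >= ep$fs / 2),
           "frequencies must lie inside (0, fs/2) = (0, %g)", ep$fs / 2)
  abort_if(any(diff(freqs) <= 0), "`freqs` must be strictly increasing")
  d <- dim(ep$data)
  S <- d[3]
  # edge margin: 3 sigma of the widest (lowest-frequency) wavelet must
  # separate the analysis interval from both epoch edges
  sigma_max_ms <- n_cycles / (2 * pi * min(freqs)) * 1000
  margin_ms <- 3 * sigma_max_ms
  t_in_ms <- epoch_times_ms(ep)
  epoch_end_ms <- t_in_ms[S] + 1000 / ep$fs
  min_dur_ms <- (crop_ms[2] - crop_ms[1]) + 2 * margin_ms
  abort_if(crop_ms[1] - t_in_ms[1] < margin_ms - 1e-6 ||
             epoch_end_ms - crop_ms[2] < margin_ms - 1e-6,
           paste("epoch too short for the %g Hz wavelet: the analysis",
                 "interval needs a %.0f ms edge margin (minimum epoch",
                 "duration %.0f ms, have %.0f ms)"),
           min(freqs), margin_ms, min_dur_ms, S / ep$fs * 1000)
  h_max <- ceiling(5 * n_cycles / (2 * pi * min(freqs)) * ep$fs)

  # Exact decimation of the convolution by spectrum folding: at 256 Hz
  # the coefficient series is subsampled by D = 2 (to >= 90 Hz and
  # >= 2*fs_out) before the power/anti-alias stage; the content this can
  # fold into the kept band lies > 4 sigma outside the wavelet bandwidth.
  native <- is.null(fs_out)
  D <- if (native) 1L else max(1L, as.integer(ep$fs %/% max(2 * fs_out, 90)))
  sub <- seq(1, S, by = D)
  t_sub_ms <- t_in_ms[sub]
  n_keep <- length(sub)
  if (native) {
    keep <- which(t_sub_ms >= crop_ms[1] - 1e-9 & t_sub_ms < crop_ms[2] - 1e-9)
    n_out <- length(keep)
    t_out_ms <- t_sub_ms[keep]
    W <- matrix(0, n_out, n_keep)
    W[cbind(seq_len(n_out), keep)] <- 1
    fs_out <- ep$fs
  } else {
    n_out <- floor((crop_ms[2] - crop_ms[1]) / 1000 * fs_out)
    t_out_ms <- crop_ms[1] + (seq_len(n_out) - 0.5) / fs_out * 1000
    W <- resample_weights(t_sub_ms / 1000, t_out_ms / 1000, ep$fs / D, fs_out)
  }

  # signals as columns: column index = (channel-1)*n_trials + trial
  sig <- matrix(aperm(ep$data, c(3, 1, 2)), nrow = S)
  n_sig <- ncol(sig)
  L <- 2 * h_max + 1
  nfft <- stats::nextn(S + L - 1, c(2, 3, 5))
  nfft <- as.integer(D * ceiling(nfft / D))     # divisible by the fold factor
  np <- nfft %/% D
  SIG <- stats::mvfft(rbind(sig, matrix(0, nfft - S, n_sig)))

  nf <- length(freqs)
  power <- array(0, c(d[1], d[2], nf, n_out))
  coefs <- if (keep_phase) array(0i, c(d[1], d[2], nf, n_out)) else NULL
  for (j in seq_len(nf)) {
    k <- morlet_kernel(freqs[j], ep$fs, n_cycles)
    hk <- (length(k) - 1L) / 2L
    # the phase term advances the convolution by hk, so row m of the
    # inverse transform is the centered coefficient at input sample 1 + D*m
    K <- stats::fft(c(k, rep(0, nfft - length(k)))) *
      exp(2i * pi * (0:(nfft - 1)) * hk / nfft)
    # the wavelet spectrum is a Gaussian around f: multiply only the
    # bins where it is non-negligible and fold them into the decimated
    # spectrum directly
    live <- which(Mod(K) > 1e-9 * max(Mod(K)))
    Cf <- matrix(0i, np, n_sig)
    # process maximal contiguous runs of live bins, split at fold-block
    # boundaries so every target row range is contiguous
    runs <- split(live, cumsum(c(1L, diff(live) != 1L)))
    for (run in runs) {
      blocks <- split(run, (run - 1L) %/% np)
      for (rows_in in blocks) {
        tgt <- ((rows_in - 1L) %% np) + 1L
        Cf[tgt, ] <- Cf[tgt, , drop = FALSE] +
          SIG[rows_in, , drop = FALSE] * K[rows_in]
      }
    }
    conv <- stats::mvfft(Cf, inverse = TRUE) / nfft
    aligned <- conv[seq_len(n_keep), , drop = FALSE]
    # clamp: the sinc resampler's negative lobes can leave tiny negative
    # excursions on a nonnegative power series
    pw <- W %*% (Re(aligned)^2 + Im(aligned)^2)
    pw[pw < 0] <- 0
    power[, , j, ] <- aperm(array(pw, c(n_out, d[1], d[2])), c(2, 3, 1))
    if (keep_phase) {
      cf <- W %*% Re(aligned) + 1i * (W %*% Im(aligned))
      coefs[, , j, ] <- aperm(array(cf, c(n_out, d[1], d[2])), c(2, 3, 1))
    }
  }
  structure(list(power = power, freqs_hz = freqs, fs_out = fs_out,
                 times_ms = t_out_ms, coefs = coefs,
                 channel_names = ep$channel_names, labels = ep$labels),
            class = "tf_power")
}

#' Aggregate time-frequency power into named frequency bands
#'
#' Band power is the sum (default, configurable to mean) of power across
#' the grid frequencies falling inside each closed band interval.
#'
#' @param tfr a `tf_power` object.
#' @param bands named list of `c(lo, hi)` Hz intervals; see
#'   [default_bands()].
#' @param agg `"sum"` (default) or `"mean"`.
#' @return a `band_power` object: `bp` array
#'   `trials x channels x bands x time`, plus band names, times, and
#'   normalization state.
#' @export
aggregate_band_power <- function(tfr, bands = default_bands(), agg = c("sum", "mean")) {
  stopifnot(inherits(tfr, "tf_power"))
  agg <- match.arg(agg)
  nb <- length(bands)
  abort_if(nb < 1 || is.null(names(bands)), "`bands` must be a named list")
  d <- dim(tfr$power)
  bp <- array(0, c(d[1], d[2], nb, d[4]))
  for (b in seq_len(nb)) {
    sel <- which(tfr$freqs_hz >= bands[[b]][1] & tfr$freqs_hz <= bands[[b]][2])
    abort_if(length(sel) == 0, "band '%s' contains no grid frequency",
             names(bands)[b])
    sub <- tfr$power[, , sel, , drop = FALSE]
    s <- rowSums(aperm(sub, c(1, 2, 4, 3)), dims = 3)  # collapse frequency axis
    bp[, , b, ] <- if (agg == "sum") s else s / length(sel)
  }
  structure(list(bp = bp, bands = bands, band_names = names(bands),
                 times_ms = tfr$times_ms, fs_out = tfr$fs_out,
                 channel_names = tfr$channel_names, labels = tfr$labels,
                 normalized = FALSE, norm_stats = NULL),
            class = "band_power")
}

#' Normalize band power to zero mean and unit SD per band
#'
#' Per band, the mean and (sample) SD are computed over the pool trials
#' across all channels and time points, then subtracted/divided for every
#' trial. The statistics are recorded so held-out trials are transformed
#' with training statistics only.
#'
#' @param bpw a `band_power` object.
#' @param pool integer trial indices defining the normalization pool
#'   (default: all trials).
#' @param stats optional `norm_stats` from a previous call; when supplied
#'   the pool is ignored and the stored statistics are applied.
#' @return a normalized `band_power` with `norm_stats` attached.
#' @export
normalize_band_power <- function(bpw, pool = NULL, stats = NULL) {
  stopifnot(inherits(bpw, "band_power"))
  d <- dim(bpw$bp)
  nb <- d[3]
  if (is.null(stats)) {
    if (is.null(pool)) pool <- seq_len(d[1])
    abort_if(length(pool) == 0, "empty normalization pool")
    stats <- data.frame(band = bpw$band_names,
                        mean = NA_real_, sd = NA_real_)
    for (b in seq_len(nb)) {
      v <- as.numeric(bpw$bp[pool, , b, ])
      stats$mean[b] <- mean(v)
      stats$sd[b] <- stats::sd(v)
      abort_if(!is.finite(stats$sd[b]) || stats$sd[b] == 0,
               "degenerate band '%s': zero SD over the normalization pool",
               bpw$band_names[b])
    }
  } else {
    abort_if(nrow(stats) != nb, "norm_stats band count mismatch")
  }
  out <- bpw
  for (b in seq_len(nb)) {
    out$bp[, , b, ] <- (bpw$bp[, , b, ] - stats$mean[b]) / stats$sd[b]
  }
  out$normalized <- TRUE
  out$norm_stats <- stats
  out
}

#' Average band power across the channels of each scalp region
#'
#' @param bpw a `band_power` object.
#' @param rmap a [region_map()] covering the channel set.
#' @return a `band_power` whose channel axis has exactly 4 entries in the
#'   fixed order frontal-left, frontal-right, posterior-left,
#'   posterior-right (unweighted member means).
#' @export
average_regions <- function(bpw, rmap) {
  stopifnot(inherits(bpw, "band_power"), inherits(rmap, "region_map"))
  idx <- region_indices(rmap, bpw$channel_names)
  d <- dim(bpw$bp)
  out_bp <- array(0, c(d[1], 4L, d[3], d[4]))
  for (r in seq_along(REGION_NAMES)) {
    sub <- bpw$bp[, idx[[r]], , , drop = FALSE]
    out_bp[, r, , ] <- rowSums(aperm(sub, c(1, 3, 4, 2)), dims = 3) /
      length(idx[[r]])
  }
  out <- bpw
  out$bp <- out_bp
  out$channel_names <- REGION_NAMES
  out
}

#' Build the overlapping analysis window grid
#'
#' Windows are half-open `[start + k*step, start + k*step + width)` ms
#' intervals, for every `k` whose window lies fully inside
#' `[start, end]`. The default configuration (0, 2000, 400, 200) yields
#' the nine windows `[0,400), [200,600), ..., [1600,2000)`.
#'
#' @param start_ms,end_ms analysis interval bounds, ms.
#' @param width_ms window width (default 400).
#' @param step_ms window step (default 200).
#' @return a `window_grid`: matrix `windows` with columns start/end, plus
#'   the parameters.
#' @export
make_window_grid <- function(start_ms = 0, end_ms = 2000,
                             width_ms = 400, step_ms = 200) {
  abort_if(width_ms <= 0 || step_ms <= 0, "width and step must be > 0")
  abort_if(width_ms > end_ms - start_ms,
           "window width exceeds the analysis interval")
  starts <- c()
  k <- 0
  repeat {
    a <- start_ms + k * step_ms
    if (a + width_ms > end_ms + 1e-9) break
    starts <- c(starts, a)
    k <- k + 1
  }
  structure(list(windows = cbind(start = starts, end = starts + width_ms),
                 width_ms = width_ms, step_ms = step_ms),
            class = "window_grid")
}

#' @export
print.window_grid <- function(x, ...) {
  cat(sprintf("<window_grid> %d windows of %g ms, step %g ms\n",
              nrow(x$windows), x$width_ms, x$step_ms))
  invisible(x)
}

# Sample indices per window: a window [a, b) holds samples with
# a <= t < b. Errors if any window maps to < min_n samples.
window_samples <- function(grid, times_ms, min_n = 2L) {
  lapply(seq_len(nrow(grid$windows)), function(w) {
    idx <- which(times_ms >= grid$windows[w, 1] - 1e-9 &
                 times_ms < grid$windows[w, 2] - 1e-9)
    abort_if(length(idx) < min_n,
             "window [%g, %g) maps to %d sample(s); need >= %d",
             grid$windows[w, 1], grid$windows[w, 2], length(idx), min_n)
    idx
  })
}

# Analytic-signal phase of a (mean-centered) series via FFT.
hilbert_phase <- function(x) {
  x <- x - mean(x)
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Arg(stats::fft(X * h, inverse = TRUE) / n)
}
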