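# Seeded synthetic epoch generator with known ground truth: 1/f
# background noise plus band-limited oscillations, with class-dependent
# amplitude or phase-coupling effects confined to chosen channels and
# time windows.

#' Specification of a synthetic epoch dataset
#'
#' The generated signal per trial and channel is 1/f-filtered Gaussian
#' noise plus sinusoidal oscillations whose per-trial frequency is drawn
#' uniformly within the band and whose phase is random. An amplitude
#' effect multiplies an oscillation's amplitude for one class inside a
#' time window on a channel subset; a phase-coupling effect shares the
#' oscillator phase across a channel subset with per-channel jitter
#' controlling the phase-locking value.
#'
#' @param n_trials named integer vector: trials per class (names are the
#'   integer class labels). Default 200/200.
#' @param channels channel names (default: the 32-channel montage).
#' @param fs sampling rate, Hz (default 256).
#' @param epoch_ms epoch interval `c(start, end)` relative to stimulus
#'   onset (default -1000..3000 so 0..2000 survives wavelet edges).
#' @param background list: `exponent` of the 1/f spectrum and RMS
#'   `amplitude` in microvolts (defaults 1 and 20).
#' @param oscillations list of `list(name, freq, bw, amplitude)`;
#'   defaults: theta 5 Hz/6 uV, alpha 10 Hz/8 uV, beta 20 Hz/4 uV,
#'   gamma 45 Hz/3 uV.
#' @param effects list of `list(class, oscillation, channels, window_ms,
#'   amp_mult)` for amplitude effects, or `list(class, oscillation,
#'   channels, window_ms, plv_jitter)` for phase coupling (jitter SD in
#'   radians). Default: alpha amplitude x2 for class 2 on the four
#'   posterior-most channels in 400..800 ms.
#' @param seed RNG seed fixing the dataset bit-exactly.
#' @return a `synthetic_spec`.
#' @export
synthetic_spec <- function(n_trials = c(`1` = 200, `2` = 200),
                           channels = default_montage(),
                           fs = 256, epoch_ms = c(-1000, 3000),
                           background = list(exponent = 1, amplitude = 20),
                           oscillations = default_oscillations(),
                           effects = default_effects(),
                           seed = 0) {
  abort_if(is.null(names(n_trials)), "`n_trials` must be named by class")
  abort_if(any(n_trials < 1), "trial counts must be >= 1")
  abort_if(background$amplitude <= 0, "background amplitude must be > 0")
  for (o in oscillations) abort_if(o$amplitude <= 0,
                                   "oscillation amplitudes must be > 0")
  for (e in effects) {
    abort_if(e$window_ms[1] < epoch_ms[1] || e$window_ms[2] > epoch_ms[2],
             "effect window outside the epoch")
    abort_if(!e$oscillation %in% vapply(oscillations, `[[`, "", "name"),
             "effect refers to unknown oscillation '%s'", e$oscillation)
    abort_if(!all(e$channels %in% channels),
             "effect channels missing from the montage")
  }
  structure(list(n_trials = n_trials, channels = channels, fs = fs,
                 epoch_ms = epoch_ms, background = background,
                 oscillations = oscillations, effects = effects,
                 seed = seed),
            class = "synthetic_spec")
}

#' @rdname synthetic_spec
#' @export
default_oscillations <- function() {
  list(list(name = "theta", freq = 5, bw = 2, amplitude = 6),
       list(name = "alpha", freq = 10, bw = 2, amplitude = 8),
       list(name = "beta", freq = 20, bw = 4, amplitude = 4),
       list(name = "gamma", freq = 45, bw = 10, amplitude = 3))
}

#' @rdname synthetic_spec
#' @export
default_effects <- function() {
  list(list(class = 2L, oscillation = "alpha",
            channels = c("PO3", "PO4", "O1", "O2"),
            window_ms = c(400, 800), amp_mult = 2))
}

# 1/f^exponent background noise, unit variance, one column per series.
pink_noise <- function(S, n_series, exponent, fs) {
  w <- matrix(stats::rnorm(S * n_series), S)
  Wf <- stats::mvfft(w)
  f <- c(0, pmin(seq_len(S - 1), S - seq_len(S - 1))) * fs / S
  g <- c(0, f[-1]^(-exponent / 2))
  x <- Re(stats::mvfft(Wf * g, inverse = TRUE)) / S
  sdx <- sqrt(colMeans(x^2) - colMeans(x)^2)
  sweep(x, 2, ifelse(sdx > 0, sdx, 1), "/")
}

#' Generate a labeled synthetic epoch set with ground truth
#'
#' @param spec a [synthetic_spec()].
#' @return list with `epochs` (an [epoch_set()]) and `truth`: for each
#'   effect, the affected (oscillation band, window, channels) cell and
#'   effect parameters, family-agnostic.
#' @export
generate_epochs <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  S <- round((spec$epoch_ms[2] - spec$epoch_ms[1]) / 1000 * spec$fs)
  t_s <- spec$epoch_ms[1] / 1000 + (seq_len(S) - 1) / spec$fs
  nch <- length(spec$channels)
  classes <- as.integer(names(spec$n_trials))
  labels <- rep(classes, times = spec$n_trials)
  n <- length(labels)
  data <- array(0, c(n, nch, S))
  with_seed(spec$seed, {
    bg <- pink_noise(S, n * nch, spec$background$exponent, spec$fs) *
      spec$background$amplitude
    data <- aperm(array(bg, c(S, n, nch)), c(2, 3, 1))
    for (o in spec$oscillations) {
      f_trial <- stats::runif(n, o$freq - o$bw / 2, o$freq + o$bw / 2)
      base_phase <- stats::runif(n, 0, 2 * pi)
      # per-channel independent phase unless a coupling effect overrides
      ch_phase <- matrix(stats::runif(n * nch, 0, 2 * pi), n, nch)
      amp <- array(o$amplitude, c(n, nch, S))
      for (e in spec$effects) {
        if (e$oscillation != o$name) next
        rows <- which(labels == e$class)
        cols <- match(e$channels, spec$channels)
        if (!is.null(e$amp_mult)) {
          in_win <- t_s * 1000 >= e$window_ms[1] & t_s * 1000 < e$window_ms[2]
          amp[rows, cols, in_win] <- o$amplitude * e$amp_mult
        }
        if (!is.null(e$plv_jitter)) {
          jit <- matrix(stats::rnorm(length(rows) * length(cols),
                                     sd = e$plv_jitter),
                        length(rows), length(cols))
          ch_phase[rows, cols] <- base_phase[rows] + jit
        }
      }
      for (ch in seq_len(nch)) {
        carrier <- sin(outer(2 * pi * f_trial, t_s) + ch_phase[, ch])
        data[, ch, ] <- data[, ch, ] + amp[, ch, ] * carrier
      }
    }
  })
  ep <- epoch_set(data, labels, spec$fs, spec$channels, spec$epoch_ms[1])
  truth <- lapply(spec$effects, function(e) {
    o <- spec$oscillations[[match(e$oscillation,
                                  vapply(spec$oscillations, `[[`, "", "name"))]]
    list(class = e$class, oscillation = e$oscillation,
         freq_range = c(o$freq - o$bw / 2, o$freq + o$bw / 2),
         channels = e$channels, window_ms = e$window_ms,
         amp_mult = e$amp_mult %||% NULL,
         plv_jitter = e$plv_jitter %||% NULL)
  })
  list(epochs = ep, truth = truth)
}

# Which default-band name contains the oscillation's center frequency.
band_of_effect <- function(truth_entry, bands = default_bands()) {
  f0 <- mean(truth_entry$freq_range)
  for (b in names(bands)) {
    if (f0 >= bands[[b]][1] && f0 <= bands[[b]][2]) return(b)
  }
  NA_character_
}

#' Ideal-observer accuracy for a single amplitude effect
#'
#' Simulates the effect cell's mean-power feature (mean normalized band
#' power of one effect channel in one analysis window inside the effect
#' interval) from a reduced single-channel run of the identical signal
#' model, fits a Gaussian per class, and returns the closed-form Bayes
#' accuracy of the two-Gaussian rule at equal priors, with the
#' Monte-Carlo standard error.
#'
#' @param spec a [synthetic_spec()] with exactly one amplitude effect.
#' @param n_draws feature draws per class (default 20000; raise toward
#'   1e6 for a tighter standard error).
#' @param window_ms analysis window (default: the first default-grid
#'   window fully inside the effect interval).
#' @param seed simulation seed (default: spec seed + 1).
#' @return list with `accuracy`, `se`, class moments, and the window
#'   used.
#' @export
analytic_bayes_accuracy <- function(spec, n_draws = 20000,
                                    window_ms = NULL, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  abort_if(length(spec$effects) != 1,
           "closed form requires exactly one effect")
  e <- spec$effects[[1]]
  abort_if(is.null(e$amp_mult), "closed form requires an amplitude effect")
  if (is.null(seed)) seed <- derive_seed(spec$seed, "bayes")
  if (is.null(window_ms)) window_ms <- e$window_ms[1] + c(0, 400)
  ch <- e$channels[1]
  bands <- default_bands()
  f0 <- spec$oscillations[[match(e$oscillation,
    vapply(spec$oscillations, `[[`, "", "name"))]]$freq
  bname <- band_of_effect(list(freq_range = c(f0, f0)), bands)
  bname <- if (is.na(bname)) "alpha" else bname

  one_class <- function(cls, n_k, sd_seed) {
    feat <- numeric(0)
    chunk <- 2000L
    done <- 0L
    while (done < n_k) {
      m <- min(chunk, n_k - done)
      sub <- synthetic_spec(
        n_trials = stats::setNames(m, cls), channels = ch,
        fs = spec$fs, epoch_ms = spec$epoch_ms,
        background = spec$background, oscillations = spec$oscillations,
        effects = if (cls == e$class) {
          list(utils::modifyList(e, list(channels = ch)))
        } else list(),
        seed = derive_seed(sd_seed, paste0("chunk", done)))
      ep <- generate_epochs(sub)$epochs
      grid1 <- make_window_grid(window_ms[1], window_ms[2],
                                window_ms[2] - window_ms[1], 400)
      freqs_band <- default_freqs()[default_freqs() >= bands[[bname]][1] &
                                    default_freqs() <= bands[[bname]][2]]
      tfr <- morlet_transform(ep, freqs_band, 5, 50.25,
                              crop_ms = window_ms)
      bpw <- aggregate_band_power(tfr, bands[bname])
      idx <- window_samples(grid1, bpw$times_ms)[[1]]
      feat <- c(feat, rowMeans(matrix(bpw$bp[, 1, 1, idx], nrow = m)))
      done <- done + m
    }
    feat
  }
  other <- setdiff(as.integer(names(spec$n_trials)), e$class)[1]
  f1 <- one_class(other, n_draws, derive_seed(seed, "c1"))
  f2 <- one_class(e$class, n_draws, derive_seed(seed, "c2"))
  m1 <- mean(f1); s1 <- stats::sd(f1)
  m2 <- mean(f2); s2 <- stats::sd(f2)
  acc <- two_gaussian_bayes_accuracy(m1, s1, m2, s2)
  # block-resampled Monte-Carlo SE of the accuracy estimate
  nb <- 10
  accs <- vapply(seq_len(nb), function(b) {
    i <- seq.int(b, length(f1), by = nb)
    two_gaussian_bayes_accuracy(mean(f1[i]), stats::sd(f1[i]),
                                mean(f2[i]), stats::sd(f2[i]))
  }, numeric(1))
  list(accuracy = acc, se = stats::sd(accs) / sqrt(nb),
       moments = c(m1 = m1, s1 = s1, m2 = m2, s2 = s2),
       window_ms = window_ms, band = bname, n_draws = n_draws)
}

# Bayes accuracy (equal priors) of the optimal rule for two univariate
# Gaussians, handling both the equal- and unequal-variance cases.
two_gaussian_bayes_accuracy <- function(m1, s1, m2, s2) {
  if (abs(s1 - s2) < 1e-12 * max(s1, s2)) {
    return(stats::pnorm(abs(m2 - m1) / (2 * max(s1, 1e-300))))
  }
  # solve log N1(x) = log N2(x): a x^2 + b x + c = 0
  a <- 1 / (2 * s2^2) - 1 / (2 * s1^2)
  b <- m1 / s1^2 - m2 / s2^2
  cc <- m2^2 / (2 * s2^2) - m1^2 / (2 * s1^2) + log(s2 / s1)
  disc <- b^2 - 4 * a * cc
  if (disc <= 0) return(0.5)
  r <- sort(c((-b - sqrt(disc)) / (2 * a), (-b + sqrt(disc)) / (2 * a)))
  # g(x) = log N1 - log N2 = a x^2 + b x + cc; class-1 region = {g > 0}.
  # a > 0 (upward parabola): positive outside the roots; a < 0: inside.
  p_in_1 <- stats::pnorm(r[2], m1, s1) - stats::pnorm(r[1], m1, s1)
  p_in_2 <- stats::pnorm(r[2], m2, s2) - stats::pnorm(r[1], m2, s2)
  if (a > 0) 0.5 * (1 - p_in_1) + 0.5 * p_in_2
  else 0.5 * p_in_1 + 0.5 * (1 - p_in_2)
}

#' Feature-space cells carrying the planted effect
#'
#' Maps the generator's ground truth onto default-configuration feature
#' descriptors: the default-band name of the effect oscillation, the
#' window indices of a [make_window_grid()] overlapping the effect
#' interval, and the effect channels.
#'
#' @param truth `truth` list from [generate_epochs()].
#' @param grid a window grid (default the standard nine windows).
#' @return data frame with columns band, window, channel.
#' @export
truth_cells <- function(truth, grid = make_window_grid()) {
  do.call(rbind, lapply(truth, function(e) {
    b <- band_of_effect(e)
    wins <- which(grid$windows[, "start"] < e$window_ms[2] &
                  grid$windows[, "end"] > e$window_ms[1])
    expand.grid(band = b, window = wins, channel = e$channels,
                stringsAsFactors = FALSE)
  }))
}
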