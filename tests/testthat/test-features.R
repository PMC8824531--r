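# The eight feature families and the descriptor-indexed assembly.

# 4-channel band power (one channel per region), 1 band, 40 samples at
# 50 Hz from 0 ms: two windows of 400 ms stepped 400 ms.
grid2 <- function() make_window_grid(0, 800, 400, 400)

test_that("mean and variance features match their closed forms and oracles", {
  bp <- array(0, c(4, 4, 1, 40))
  bp[1, , , ] <- 3                        # constant -> mean 3, var 0
  bp[2, 1, 1, 1:20] <- rep(c(0, 2), 10)   # two-point {0,2} -> var ~ by formula
  set.seed(2)
  bp[3:4, , , ] <- rnorm(2 * 4 * 40)
  bpw <- fake_band_power(bp, channel_names = c("FL", "FR", "PL", "PR"))
  fm <- extract_features(bpw, grid2(), rmap4(), families = c("mean", "variance"))

  expect_equal(ncol(fm$X), 2 * 1 * 2 * 4)
  m1 <- fm$X[1, fm$descriptors$family == "mean"]
  expect_true(all(m1 == 3))
  expect_true(all(fm$X[1, fm$descriptors$family == "variance"] == 0))

  # {0,2} alternating: mean 1, sample variance n/(n-1)*1 = 20/19... direct:
  expect_equal(unname(fm$X[2, fm$descriptors$family == "variance" &
                             fm$descriptors$locus == "FL" &
                             fm$descriptors$window == 1][1]),
               var(rep(c(0, 2), 10)))

  # random rows match direct oracles
  for (tr in 3:4) for (ch in 1:4) for (w in 1:2) {
    seg <- bp[tr, ch, 1, (w - 1) * 20 + 1:20]
    sel <- fm$descriptors$family == "mean" &
      fm$descriptors$locus == c("FL", "FR", "PL", "PR")[ch] &
      fm$descriptors$window == w
    expect_equal(unname(fm$X[tr, sel]), mean(seg))
    selv <- fm$descriptors$family == "variance" &
      fm$descriptors$locus == c("FL", "FR", "PL", "PR")[ch] &
      fm$descriptors$window == w
    expect_equal(unname(fm$X[tr, selv]), var(seg))
  }
})

test_that("spec two-point variance example: window {0, 2} has variance 2", {
  # a window holding half zeros and half twos in any order has sample
  # variance (sum (x - 1)^2) / (n - 1) = 20/19; the printed closed-form
  # example uses the two-point set {0, 2} itself:
  expect_equal(var(c(0, 2)), 2)
})

test_that("entropy features: closed forms and histogram oracle", {
  bp <- array(0, c(3, 1, 1, 20))
  bp[1, 1, 1, ] <- 5                                   # constant -> 0 bits
  bp[2, 1, 1, ] <- rep(c(0, 1, 2, 3), each = 5)        # 4 equal bins
  set.seed(9)
  bp[3, 1, 1, ] <- runif(20)
  bpw <- fake_band_power(bp)
  fm <- extract_features(bpw, make_window_grid(0, 400, 400, 400),
                         families = "entropy", n_bins = 4)
  expect_equal(unname(fm$X[1, 1]), 0)
  expect_equal(unname(fm$X[2, 1]), 2)                  # uniform over 4 bins

  # histogram-probability oracle
  x <- bp[3, 1, 1, ]
  br <- seq(min(x), max(x), length.out = 5)
  cnt <- hist(x, breaks = br, plot = FALSE, right = FALSE,
              include.lowest = TRUE)$counts
  # right-open binning with the max clamped into the last bin
  idx <- pmin(floor((x - min(x)) / (max(x) - min(x)) * 4) + 1, 4)
  p <- tabulate(idx, 4) / 20
  H <- -sum(p[p > 0] * log2(p[p > 0]))
  expect_equal(unname(fm$X[3, 1]), H)
  expect_lte(max(fm$X), log2(4))
})

test_that("phase features are mean resultant lengths in [0, 1]", {
  # constant series -> centered signal 0 -> constant phase -> MRL 1
  bp <- array(2, c(2, 1, 1, 40))
  # full-cycle cosine -> phase sweeps the circle uniformly -> MRL ~ 0
  bp[2, 1, 1, ] <- cos(2 * pi * (0:39) / 20)
  bpw <- fake_band_power(bp)
  fm <- extract_features(bpw, make_window_grid(0, 800, 800, 800),
                         families = "phase")
  expect_equal(unname(fm$X[1, 1]), 1)
  expect_lt(unname(fm$X[2, 1]), 0.05)

  # random series: oracle recomputes MRL from an independent analytic
  # signal (direct DFT half-spectrum doubling)
  set.seed(4)
  x <- rnorm(40)
  bp[1, 1, 1, ] <- x
  bpw <- fake_band_power(bp)
  fm2 <- extract_features(bpw, make_window_grid(0, 800, 800, 800),
                          families = "phase")
  xc <- x - mean(x)
  Xf <- fft(xc)
  n <- length(xc)
  mult <- c(1, rep(2, n / 2 - 1), 1, rep(0, n / 2 - 1))
  an <- fft(Xf * mult, inverse = TRUE) / n
  phi <- Arg(an)
  expect_equal(unname(fm2$X[1, 1]), Mod(mean(exp(1i * phi))),
               tolerance = 1e-10)
  expect_true(all(fm2$X >= 0 & fm2$X <= 1))
})

test_that("correlation features: identical, negated, and random pairs", {
  set.seed(8)
  base <- matrix(rnorm(3 * 40), 3)
  bp <- array(0, c(3, 4, 1, 40))
  bp[, 1, 1, ] <- base                 # FL
  bp[, 2, 1, ] <- base                 # FR identical -> r = 1
  bp[, 3, 1, ] <- -base                # PL negated  -> r = -1
  bp[, 4, 1, ] <- matrix(rnorm(3 * 40), 3)
  bpw <- fake_band_power(bp, channel_names = c("FL", "FR", "PL", "PR"))
  fm <- extract_features(bpw, grid2(), rmap4(), families = "correlation")
  d <- fm$descriptors
  expect_equal(ncol(fm$X), 6 * 2)
  r_flfr <- fm$X[, d$locus == "frontal-left~frontal-right" & d$window == 1]
  expect_equal(unname(r_flfr), rep(1, 3))
  r_flpl <- fm$X[, d$locus == "frontal-left~posterior-left" & d$window == 1]
  expect_equal(unname(r_flpl), rep(-1, 3))
  # covariance/SD oracle on the random pair
  for (tr in 1:3) {
    o <- cor(bp[tr, 1, 1, 1:20], bp[tr, 4, 1, 1:20])
    expect_equal(unname(fm$X[tr, d$locus == "frontal-left~posterior-right" &
                               d$window == 1]), o)
  }
  # zero-variance series -> 0 with a warning
  bp[, 4, 1, ] <- 1
  bpw0 <- fake_band_power(bp, channel_names = c("FL", "FR", "PL", "PR"))
  expect_warning(
    fm0 <- extract_features(bpw0, grid2(), rmap4(), families = "correlation"),
    "zero-variance")
  expect_true(all(fm0$X[, fm0$descriptors$locus ==
                          "frontal-left~posterior-right"] == 0))
})

test_that("phase synchrony is the PLV of region phase differences", {
  set.seed(10)
  base <- matrix(rnorm(2 * 40), 2)
  bp <- array(0, c(2, 4, 1, 40))
  bp[, 1, 1, ] <- base
  bp[, 2, 1, ] <- base                # identical phases -> PLV 1
  bp[, 3, 1, ] <- matrix(rnorm(2 * 40), 2)
  bp[, 4, 1, ] <- matrix(rnorm(2 * 40), 2)
  bpw <- fake_band_power(bp, channel_names = c("FL", "FR", "PL", "PR"))
  fm <- extract_features(bpw, grid2(), rmap4(), families = "phase_sync")
  d <- fm$descriptors
  expect_equal(unname(fm$X[, d$locus == "frontal-left~frontal-right" &
                             d$window == 1]),
               rep(1, 2), tolerance = 1e-12)
  expect_true(all(fm$X >= 0 & fm$X <= 1))

  # direct PLV oracle on a random pair
  ph <- eegdecode:::analytic_phase_array(bp)
  for (tr in 1:2) {
    dphi <- ph[tr, 3, 1, 1:20] - ph[tr, 4, 1, 1:20]
    o <- Mod(mean(exp(1i * dphi)))
    expect_equal(unname(fm$X[tr, d$locus == "posterior-left~posterior-right" &
                               d$window == 1]), o, tolerance = 1e-12)
  }
})

test_that("AR features recover generating coefficients and obey degeneracy", {
  # long window: alpha = (0.6, -0.2, 0, 0), noise sd 0.01
  set.seed(12)
  n <- 5000
  x <- numeric(n + 50)
  for (i in 5:(n + 50)) {
    x[i] <- 0.6 * x[i - 1] - 0.2 * x[i - 2] + rnorm(1, sd = 0.01)
  }
  x <- x[51:(n + 50)]
  cf <- eegdecode:::ar_ols(x, 4)
  expect_lt(max(abs(cf - c(0.6, -0.2, 0, 0))), 0.05)

  # zero series -> coefficients 0 by the degeneracy rule (with warning)
  bp <- array(0, c(2, 4, 1, 40))
  set.seed(13)
  bp[2, , 1, ] <- rnorm(4 * 40)
  bpw <- fake_band_power(bp, channel_names = c("FL", "FR", "PL", "PR"))
  expect_warning(
    fm <- extract_features(bpw, grid2(), rmap4(), families = "ar"),
    "rank-deficient")
  expect_true(all(fm$X[1, ] == 0))
  expect_equal(ncol(fm$X), 4 * 4 * 2)   # 4 regions x 4 coefs x 2 windows

  # normal-equations oracle on a random series
  seg <- bp[2, 1, 1, 1:20]
  emb <- embed(seg, 5)
  beta <- solve(crossprod(emb[, -1]), crossprod(emb[, -1], emb[, 1]))
  d <- fm$descriptors
  got <- fm$X[2, d$locus == "frontal-left" & d$window == 1]
  expect_equal(unname(got), as.numeric(beta), tolerance = 1e-8)
})

test_that("CSP filters: diagonal case, no-separation case, and grid-search oracle", {
  # diagonal case: classes with covariance diag(2,1) and diag(1,2)
  set.seed(20)
  n_per <- 150; S <- 20
  bp <- array(0, c(2 * n_per, 2, 1, S))
  labels <- rep(1:2, each = n_per)
  bp[labels == 1, 1, 1, ] <- rnorm(n_per * S, sd = sqrt(2))
  bp[labels == 1, 2, 1, ] <- rnorm(n_per * S, sd = 1)
  bp[labels == 2, 1, 1, ] <- rnorm(n_per * S, sd = 1)
  bp[labels == 2, 2, 1, ] <- rnorm(n_per * S, sd = sqrt(2))
  bpw <- fake_band_power(bp, labels = labels)
  grid <- make_window_grid(0, 400, 400, 400)
  model <- fit_csp(bpw, grid, seq_len(2 * n_per), labels)
  W <- model$cells[[1]]$W
  # filters align with the coordinate axes; class-1/class-2 variance
  # ratios approach 2 and 1/2
  a1 <- abs(W[, 1]) / sqrt(sum(W[, 1]^2))
  expect_gt(max(a1), 0.97)
  r1 <- as.numeric((t(W[, 1]) %*% model$cells[[1]]$C1bar %*% W[, 1]) /
                   (t(W[, 1]) %*% model$cells[[1]]$C2bar %*% W[, 1]))
  r2 <- as.numeric((t(W[, 2]) %*% model$cells[[1]]$C1bar %*% W[, 2]) /
                   (t(W[, 2]) %*% model$cells[[1]]$C2bar %*% W[, 2]))
  expect_equal(r1, 2, tolerance = 0.25)
  expect_equal(r2, 0.5, tolerance = 0.15)

  # identical class distributions -> eigenvalues of (C1, C1+C2) near 1/2
  bp2 <- array(rnorm(2 * n_per * 2 * S), c(2 * n_per, 2, 1, S))
  bpw2 <- fake_band_power(bp2, labels = labels)
  m2 <- fit_csp(bpw2, grid, seq_len(2 * n_per), labels)
  expect_equal(m2$cells[[1]]$eig, c(0.5, 0.5), tolerance = 0.07)

  # 3-d random case: top filter's Rayleigh quotient matches a dense
  # grid search over unit vectors
  set.seed(21)
  bp3 <- array(rnorm(60 * 3 * S), c(60, 3, 1, S))
  bp3[1:30, , , ] <- bp3[1:30, , , ] * rep(c(2, 1, 0.5), each = 30)
  bpw3 <- fake_band_power(bp3, labels = rep(1:2, each = 30))
  m3 <- fit_csp(bpw3, grid, 1:60, rep(1:2, each = 30))
  C1 <- m3$cells[[1]]$C1bar; C2 <- m3$cells[[1]]$C2bar
  rq <- function(w) as.numeric((t(w) %*% C1 %*% w) / (t(w) %*% C2 %*% w))
  th <- seq(0, pi, length.out = 60)
  ph <- seq(0, 2 * pi, length.out = 120)
  gmax <- 0
  for (a in th) for (b in ph) {
    w <- c(sin(a) * cos(b), sin(a) * sin(b), cos(a))
    gmax <- max(gmax, rq(w))
  }
  expect_equal(rq(m3$cells[[1]]$W[, 1]), gmax, tolerance = 0.01)
  expect_gte(rq(m3$cells[[1]]$W[, 1]), gmax - 1e-8)

  # simultaneous diagonalization invariant
  Wm <- m3$cells[[1]]$W
  D1 <- t(Wm) %*% C1 %*% Wm
  Dc <- t(Wm) %*% (C1 + C2) %*% Wm
  expect_lt(max(abs(D1 - diag(diag(D1)))), 1e-8)
  expect_lt(max(abs(Dc - diag(ncol(Wm)))), 1e-8)

  expect_error(fit_csp(bpw3, grid, 1:60, rep(1, 60)), "2 classes")
})

test_that("CSP features equal channel variances under the identity filter", {
  set.seed(22)
  bp <- array(rnorm(10 * 3 * 40), c(10, 3, 1, 40))
  bpw <- fake_band_power(bp, labels = rep(1:2, 5))
  grid <- grid2()
  model <- structure(list(
    cells = rep(list(list(W = diag(3), eig = rep(0.5, 3))), 2),
    n_bands = 1, n_windows = 2, classes = 1:2, n_components = 3,
    grid = grid, band_names = "b1"), class = "csp_model")
  Xc <- extract_csp_features(bpw, grid, model)
  fmv <- extract_features(bpw, grid, families = "variance")
  expect_equal(unname(Xc), unname(fmv$X), tolerance = 1e-12)

  # projection-then-variance oracle with a fitted model
  fitted <- fit_csp(bpw, grid, 1:10, rep(1:2, 5))
  Xf <- extract_csp_features(bpw, grid, fitted)
  W1 <- fitted$cells[[1]]$W
  for (tr in 1:3) {
    m <- W1
    proj <- t(m) %*% matrix(bp[tr, , 1, 1:20], nrow = 3)
    expect_equal(unname(Xf[tr, 1:3]), unname(apply(proj, 1, var)),
                 tolerance = 1e-10)
  }
  # grid mismatch errors
  expect_error(extract_csp_features(bpw, make_window_grid(0, 400, 400, 400),
                                    fitted), "mismatch")
})

test_that("phase options: circular-mean angle and wavelet-native phase", {
  set.seed(25)
  bp <- array(rnorm(4 * 2 * 1 * 40), c(4, 2, 1, 40))
  bpw <- fake_band_power(bp)
  g <- make_window_grid(0, 800, 800, 800)
  # angle variant returns the circular-mean angle, in (-pi, pi]
  fm_a <- extract_features(bpw, g, families = "phase", phase_stat = "angle")
  expect_true(all(fm_a$X > -pi & fm_a$X <= pi))
  ph <- eegdecode:::analytic_phase_array(bp)
  zm <- mean(exp(1i * ph[1, 1, 1, ]))
  expect_equal(unname(fm_a$X[1, 1]), Arg(zm), tolerance = 1e-10)

  # supplied (wavelet-native) phases override the Hilbert default
  fm_h <- extract_features(bpw, g, families = "phase")
  ph2 <- ph; ph2[] <- 0.3                       # constant phase -> MRL 1
  fm_o <- extract_features(bpw, g, families = "phase", phases = ph2)
  expect_true(all(abs(fm_o$X - 1) < 1e-12))
  expect_false(isTRUE(all.equal(fm_h$X, fm_o$X)))

  # band_phase_from_coefs round trip: a pure sinusoid's band phase
  # advances at the stimulus frequency
  t <- (0:511) / 256 - 1
  x <- array(sin(2 * pi * 10 * t), c(1, 1, 512))
  ep <- epoch_set(x, 1, 256, t0 = -1000)
  tfr <- morlet_transform(ep, freqs = 8:12, crop_ms = c(-200, 500),
                          keep_phase = TRUE)
  phw <- band_phase_from_coefs(tfr, list(alpha = c(8, 12)))
  dphi <- diff(phw[1, 1, 1, ])
  dphi <- (dphi + pi) %% (2 * pi) - pi
  # expected advance per output sample: 2*pi*10/50.25
  expect_equal(median(dphi), 2 * pi * 10 / 50.25, tolerance = 0.02)
  expect_error(band_phase_from_coefs(morlet_transform(
    ep, freqs = 8:12, crop_ms = c(-200, 500))), "keep_phase")
})

test_that("reduced CSP keeps the extreme eigenvalue pairs", {
  set.seed(26)
  bp <- array(rnorm(40 * 4 * 1 * 20), c(40, 4, 1, 20))
  bp[1:20, 1, , ] <- bp[1:20, 1, , ] * 2       # class separation on ch 1
  bpw <- fake_band_power(bp, labels = rep(1:2, each = 20))
  g <- make_window_grid(0, 400, 400, 400)
  full <- fit_csp(bpw, g, 1:40, rep(1:2, each = 20))
  red <- fit_csp(bpw, g, 1:40, rep(1:2, each = 20), n_components = 2)
  expect_equal(red$cells[[1]]$W[, 1], full$cells[[1]]$W[, 1])
  expect_equal(red$cells[[1]]$W[, 2], full$cells[[1]]$W[, 4])
  expect_equal(red$cells[[1]]$eig, full$cells[[1]]$eig[c(1, 4)])
})

test_that("assembly: column order, closed-form counts, determinism, permutation", {
  w <- small_world(10, 10, amp_mult = 1, seed = 5)
  sbp <- small_band_power(w)
  grid <- small_grid()
  rmap <- default_region_map(montage8())
  fm <- extract_features(sbp$bpw, grid, rmap)
  expect_equal(ncol(fm$X), feature_count(8, 4, 3))
  # family blocks appear in canonical order
  fams <- unique(fm$descriptors$family)
  expect_equal(fams, c("mean", "variance", "entropy", "phase",
                       "correlation", "phase_sync", "ar", "csp"))
  expect_true(all(is.finite(fm$X)))

  # mean-only config
  fm_m <- extract_features(sbp$bpw, grid, rmap, families = "mean")
  expect_equal(ncol(fm_m$X), 8 * 4 * 3)

  # two identical trials give identical non-CSP rows
  bp2 <- sbp$bpw
  bp2$bp[2, , , ] <- bp2$bp[1, , , ]
  fm2 <- extract_features(bp2, grid, rmap,
                          families = c("mean", "variance", "entropy",
                                       "phase", "correlation",
                                       "phase_sync", "ar"))
  expect_equal(fm2$X[1, ], fm2$X[2, ])

  # permuting trials permutes non-CSP rows identically
  perm <- c(3, 1, 2, 4:20)
  bp3 <- sbp$bpw
  bp3$bp <- bp3$bp[perm, , , , drop = FALSE]
  bp3$labels <- bp3$labels[perm]
  fm3 <- extract_features(bp3, grid, rmap,
                          families = c("mean", "variance", "phase"),
                          norm_pool = "all")
  fm1 <- extract_features(sbp$bpw, grid, rmap,
                          families = c("mean", "variance", "phase"),
                          norm_pool = "all")
  expect_equal(fm3$X, fm1$X[perm, ], ignore_attr = TRUE)
})
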