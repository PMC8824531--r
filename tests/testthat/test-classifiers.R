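# The four classifiers and the unified predict contract.

test_that("naive Bayes: symmetric Gaussians and the log-density oracle", {
  set.seed(50)
  n <- 2000
  X <- rbind(matrix(rnorm(n, 1), n / 2, 2) * 0 + cbind(rnorm(n / 2, 1), rnorm(n / 2)),
             cbind(rnorm(n / 2, -1), rnorm(n / 2)))
  y <- rep(1:2, each = n / 2)
  m <- train_naive_bayes(X, y)
  # boundary near x1 = 0: score depends on x1 with slope ~ |2| and
  # near-zero x2 dependence (positive class sits at x1 = -1)
  p <- predict(m, rbind(c(0.5, 0), c(-0.5, 0), c(0.5, 3)))
  expect_equal(p$labels[1], 1)
  expect_equal(p$labels[2], 2)
  expect_equal(p$labels[3], 1)
  # score ~ d2 - d1 = -2 x1 for exact unit covariances
  expect_equal(p$scores[1], -2 * 0.5, tolerance = 0.15)

  # a test point at a class mean of well-separated classes gets its label
  gf <- gaussian_features(n_per_class = 20, p = 3, delta = 8, seed = 51)
  m2 <- train_naive_bayes(gf$X, gf$labels)
  mu2 <- colMeans(gf$X[gf$labels == 2, ])
  expect_equal(predict(m2, rbind(mu2))$labels, 2)

  # discriminant equals multivariate-normal log-density + log prior
  set.seed(52)
  X3 <- matrix(rnorm(60 * 3), 60, 3)
  y3 <- rep(1:2, c(20, 40))
  m3 <- train_naive_bayes(X3, y3)
  pts <- matrix(rnorm(15), 5, 3)
  d <- eegdecode:::nb_discriminants(m3, pts)
  for (cl in 1:2) {
    mu <- colMeans(X3[y3 == cl, ]); S <- cov(X3[y3 == cl, ])
    Sinv <- solve(S)
    for (i in 1:5) {
      ld <- -0.5 * t(pts[i, ] - mu) %*% Sinv %*% (pts[i, ] - mu) -
        0.5 * log(det(S)) + log(mean(y3 == cl))
      # shared constant: -p/2 log(2*pi)
      expect_equal(unname(d[i, cl]), as.numeric(ld), tolerance = 1e-8)
    }
  }
  expect_error(train_naive_bayes(X3[1:21, ], rep(c(1, 2), c(20, 1))),
               "< 2 trials")
})

test_that("LASSO: penalty-free limit, shutdown, and 2-D grid-search oracle", {
  set.seed(53)
  n <- 50
  X <- matrix(rnorm(n * 2), n, 2)
  y <- rep(c(1, 2), each = n / 2)
  yy <- ifelse(y == 2, 1, -1)

  # lambda = 0 -> least squares
  m0 <- train_lasso(X, y, lambda = 0)
  ls <- coef(lm(yy ~ X))
  expect_equal(m0$intercept, unname(ls[1]), tolerance = 1e-6)
  expect_equal(m0$beta, unname(ls[-1]), tolerance = 1e-6)

  # lambda >= lambda_max -> all-zero coefficients, scores = intercept
  lam_max <- max(abs(crossprod(X, yy - mean(yy)))) / n
  mmax <- train_lasso(X, y, lambda = lam_max * 1.01)
  expect_equal(mmax$beta, c(0, 0))
  expect_equal(unique(predict(mmax, X)$scores), mmax$intercept)

  # dense 2-D grid search on the (1/(2n)) objective: with the intercept
  # profiled out the objective is an explicit quadratic in beta
  lam <- lam_max / 4
  mfit <- train_lasso(X, y, lambda = lam)
  yc <- yy - mean(yy)
  Xc <- sweep(X, 2, colMeans(X))
  G <- crossprod(Xc); h <- crossprod(Xc, yc); cc <- sum(yc^2)
  obj_grid <- function(b1s, b2s) {
    outer(b1s, b2s, function(b1, b2) {
      (cc - 2 * (b1 * h[1] + b2 * h[2]) +
         G[1, 1] * b1^2 + 2 * G[1, 2] * b1 * b2 + G[2, 2] * b2^2) / (2 * n) +
        lam * (abs(b1) + abs(b2))
    })
  }
  bs <- seq(-1, 1, by = 0.002)
  vals <- obj_grid(bs, bs)
  best <- arrayInd(which.min(vals), dim(vals))
  # refine around the coarse argmin
  b1f <- bs[best[1]] + seq(-0.003, 0.003, by = 1e-4)
  b2f <- bs[best[2]] + seq(-0.003, 0.003, by = 1e-4)
  vf <- obj_grid(b1f, b2f)
  bf <- arrayInd(which.min(vf), dim(vf))
  expect_lt(abs(mfit$beta[1] - b1f[bf[1]]), 1e-3)
  expect_lt(abs(mfit$beta[2] - b2f[bf[2]]), 1e-3)
  expect_lte(obj_grid(mfit$beta[1], mfit$beta[2])[1], min(vf) + 1e-9)

  # inner-CV lambda selection runs and is deterministic under a seed
  gf <- gaussian_features(n_per_class = 20, p = 5, seed = 54)
  a <- train_lasso(gf$X, gf$labels, seed = 1)
  b <- train_lasso(gf$X, gf$labels, seed = 1)
  expect_identical(a$lambda, b$lambda)
  expect_identical(a$beta, b$beta)
  expect_error(train_lasso(X, rep(1, n)), "2 classes")
})

test_that("logistic regression: symmetry, first-order condition, stationarity", {
  set.seed(55)
  n <- 60
  X1 <- matrix(rnorm(n * 2), n, 2) + 1.5
  X <- rbind(X1, -X1)                    # mirrored through the origin
  y <- rep(1:2, each = n)
  m <- train_logistic(X, y)
  expect_lt(abs(m$intercept), 1e-6)

  # mean fitted probability equals the positive base rate
  eta <- as.numeric(X %*% m$w) + m$intercept
  p_hat <- 1 / (1 + exp(-eta))
  expect_equal(mean(p_hat), mean(y == 2), tolerance = 1e-6)

  # stationarity of the penalized log-likelihood on random data
  set.seed(56)
  Xr <- matrix(rnorm(80 * 3), 80, 3)
  yr <- rep(1:2, 40)
  mr <- train_logistic(Xr, yr)
  yb <- as.numeric(yr == 2)
  etar <- as.numeric(Xr %*% mr$w) + mr$intercept
  mur <- 1 / (1 + exp(-etar))
  g <- c(sum(mur - yb), as.numeric(crossprod(Xr, mur - yb)) + 1e-6 * mr$w)
  expect_lt(max(abs(g)), 1e-6)
})


test_that("linear SVM: closed forms and the small-QP dual oracle", {
  # two separable 1-D points with large C: w = 1, b = 0, M = 2
  m <- train_linear_svm(cbind(c(-1, 1)), c(1, 2), C = 100)
  expect_equal(m$w, 1, tolerance = 1e-6)
  expect_equal(m$intercept, 0, tolerance = 1e-6)
  expect_equal(m$margin, 2, tolerance = 1e-6)

  # duplicating every trial (with the cost rescaled so the objective is
  # a pure scaling) leaves the hyperplane unchanged
  set.seed(57)
  X <- matrix(rnorm(20 * 2), 20, 2)
  y <- rep(1:2, each = 10)
  X[y == 2, ] <- X[y == 2, ] + 1.5
  m1 <- train_linear_svm(X, y, C = 1)
  m2 <- train_linear_svm(rbind(X, X), c(y, y), C = 0.5)
  expect_equal(m1$w, m2$w, tolerance = 1e-4)
  expect_equal(m1$intercept, m2$intercept, tolerance = 1e-4)

  # small problems match the exhaustive active-set dual oracle
  for (seed in 1:3) {
    set.seed(seed)
    Xs <- matrix(rnorm(12), 6, 2)
    ys <- rep(c(-1, 1), 3)
    Xs[ys == 1, ] <- Xs[ys == 1, ] + 1
    ms <- train_linear_svm(Xs, ifelse(ys > 0, 2, 1), C = 1)
    orc <- svm_dual_oracle(Xs, ys, C = 1)
    dual_fit <- 0.5 * t(ms$alpha) %*% (tcrossprod(Xs) * tcrossprod(ys)) %*%
      ms$alpha - sum(ms$alpha)
    expect_equal(as.numeric(dual_fit), orc$obj, tolerance = 1e-4)
    w_orc <- as.numeric(crossprod(Xs, orc$alpha * ys))
    expect_equal(ms$w, w_orc, tolerance = 1e-3)
  }
  expect_error(train_linear_svm(X, rep(2, 20)), "2 classes")
})

test_that("unified predict contract: reproduction, monotonicity, dimension checks", {
  gf <- gaussian_features(n_per_class = 15, p = 4, delta = 6, seed = 58)
  for (kind in c("naive_bayes", "lasso", "logistic", "linear_svm")) {
    m <- train_classifier(classifier_spec(kind), gf$X, gf$labels)
    p <- predict(m, gf$X)
    # separable training data is reproduced
    expect_equal(p$labels, gf$labels, info = kind)
    expect_error(predict(m, gf$X[, 1:3]), "mismatch")
  }
  # moving along +w never decreases the score for the linear models
  for (kind in c("lasso", "logistic", "linear_svm")) {
    m <- train_classifier(classifier_spec(kind), gf$X, gf$labels)
    w <- if (kind == "lasso") m$beta else m$w
    x0 <- gf$X[1, ]
    s <- predict(m, rbind(x0, x0 + w, x0 + 2 * w))$scores
    expect_true(all(diff(s) >= 0), info = kind)
  }
})

test_that("classifiers are invariant to trial order", {
  gf <- gaussian_features(n_per_class = 20, p = 3, delta = 1.5, seed = 59)
  set.seed(60)
  perm <- sample(length(gf$labels))
  for (kind in c("naive_bayes", "logistic", "linear_svm")) {
    m1 <- train_classifier(classifier_spec(kind), gf$X, gf$labels)
    m2 <- train_classifier(classifier_spec(kind), gf$X[perm, ],
                           gf$labels[perm])
    w1 <- if (kind == "naive_bayes") m1$pars[[1]]$mu else m1$w
    w2 <- if (kind == "naive_bayes") m2$pars[[1]]$mu else m2$w
    expect_equal(w1, w2, tolerance = 1e-6, info = kind)
  }
  # lasso at fixed lambda (the inner-CV fold assignment is the one
  # intentionally order-dependent step)
  l1 <- train_lasso(gf$X, gf$labels, lambda = 0.05)
  l2 <- train_lasso(gf$X[perm, ], gf$labels[perm], lambda = 0.05)
  expect_equal(l1$beta, l2$beta, tolerance = 1e-8)
})

test_that("balanced accuracy approaches the analytic Bayes accuracy", {
  # two Gaussians, Sigma = I, ||mu1 - mu2|| = 2 -> Bayes = pnorm(1)
  set.seed(61)
  n <- 2000
  p <- 2
  mk <- function(n) {
    X <- rbind(matrix(rnorm(n / 2 * p), n / 2, p),
               matrix(rnorm(n / 2 * p, mean = 2 / sqrt(p)), n / 2, p))
    list(X = X, y = rep(1:2, each = n / 2))
  }
  tr <- mk(n); te <- mk(4000)
  bayes <- pnorm(1)
  for (kind in c("naive_bayes", "lasso", "logistic", "linear_svm")) {
    m <- train_classifier(classifier_spec(kind), tr$X, tr$y)
    acc <- balanced_accuracy(te$y, predict(m, te$X)$labels)
    expect_lt(abs(acc - bayes), 0.03)
  }
})

test_that("model serialization writes valid JSON", {
  gf <- gaussian_features(n_per_class = 10, p = 2, n_informative = 2,
                          seed = 62)
  f <- tempfile(fileext = ".json")
  for (kind in c("naive_bayes", "lasso", "logistic", "linear_svm")) {
    m <- train_classifier(classifier_spec(kind), gf$X, gf$labels)
    write_model(m, f)
    j <- jsonlite::read_json(f, simplifyVector = TRUE)
    expect_equal(j$kind, kind)
    expect_equal(j$classes, 1:2)
  }
  unlink(f)
})
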