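# The four classifiers behind one train/score/predict contract.
#
# Binary class coding is uniform: classes are sorted and the second one is
# "positive"; scores are oriented so larger values mean stronger evidence
# for the positive class, and the decision threshold is 0.

#' Classifier specification
#'
#' A lightweight description of a classifier kind plus hyperparameters,
#' passed around by the selection wrapper, pipelines and multiclass
#' schemes.
#'
#' @param kind one of `"naive_bayes"`, `"lasso"`, `"logistic"`,
#'   `"linear_svm"`.
#' @param ... hyperparameters: `C` (SVM, default 1), `n_lambda`/`cv_folds`
#'   (LASSO, defaults 20/5), `diagonal` (naive Bayes, default FALSE =
#'   full per-class covariances as printed), `seed`.
#' @return a `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("naive_bayes", "lasso", "logistic",
                                     "linear_svm"), ...) {
  kind <- match.arg(kind)
  structure(list(kind = kind, params = list(...)), class = "classifier_spec")
}

#' Train a classifier from a specification
#' @param spec a [classifier_spec()].
#' @param X trials x features matrix.
#' @param labels per-trial classes.
#' @param seed seed for any inner randomness (LASSO CV folds).
#' @return an `eegdecode_model`.
#' @export
train_classifier <- function(spec, X, labels, seed = 0) {
  p <- spec$params
  switch(spec$kind,
    naive_bayes = train_naive_bayes(X, labels,
                                    diagonal = isTRUE(p$diagonal)),
    lasso = train_lasso(X, labels,
                        n_lambda = p$n_lambda %||% 20,
                        cv_folds = p$cv_folds %||% 5,
                        seed = p$seed %||% seed),
    logistic = train_logistic(X, labels),
    linear_svm = train_linear_svm(X, labels, C = p$C %||% 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_model <- function(kind, classes, ...) {
  structure(c(list(kind = kind, classes = classes), list(...)),
            class = c(paste0("eegdecode_", kind), "eegdecode_model"))
}

#' @export
print.eegdecode_model <- function(x, ...) {
  cat(sprintf("<%s model> classes: %s\n", x$kind,
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

check_binary <- function(labels) {
  classes <- sort(unique(labels))
  abort_if(length(classes) != 2,
           "binary classifier: need exactly 2 classes, got %d",
           length(classes))
  classes
}

# ---------------------------------------------------------------------------
# Naive Bayes (Gaussian, full per-class covariance as printed; a true
# diagonal-covariance mode is available)

#' Train the Gaussian (quadratic-discriminant) naive Bayes classifier
#'
#' Per class i the sample mean `mu_i`, covariance `Sigma_i` (ridge
#' `eps*I` added when any eigenvalue falls below 1e-10) and prior
#' `P_i` (class fraction) give the quadratic discriminant
#' `d_i(x) = x'A_i x + b_i'x + c_i` with `A_i = -0.5 Sigma_i^{-1}`,
#' `b_i = Sigma_i^{-1} mu_i`,
#' `c_i = -0.5 mu_i'Sigma_i^{-1}mu_i - 0.5 log|Sigma_i| + log P_i`.
#' The label is `argmax_i d_i(x)`; the binary voting score is
#' `d_pos(x) - d_neg(x)`.
#'
#' @param X trials x features matrix (>= 2 trials per class).
#' @param labels classes (2 or more).
#' @param diagonal use diagonal covariances (classic naive Bayes);
#'   default FALSE.
#' @return an `eegdecode_model`.
#' @export
train_naive_bayes <- function(X, labels, diagonal = FALSE) {
  classes <- sort(unique(labels))
  abort_if(length(classes) < 2, "need >= 2 classes")
  n <- nrow(X); p <- ncol(X)
  pars <- lapply(classes, function(cl) {
    sub <- X[labels == cl, , drop = FALSE]
    abort_if(nrow(sub) < 2, "class %s has < 2 trials", cl)
    mu <- colMeans(sub)
    if (diagonal) {
      # fast path: no full covariance or eigendecomposition needed
      v <- apply(sub, 2, stats::var)
      if (min(v) < 1e-10) v <- v + 1e-8 + 1e-6 * mean(v)
      S <- diag(v, p)
      Sinv <- diag(1 / v, p)
      logdet <- sum(log(v))
    } else {
      S <- stats::cov(sub)
      ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < 1e-10) {
        S <- S + diag(1e-8 + 1e-6 * mean(diag(S)), p)
      }
      R <- tryCatch(chol(S), error = function(e) NULL)
      abort_if(is.null(R), "singular class covariance after ridge")
      Sinv <- chol2inv(R)
      logdet <- 2 * sum(log(diag(R)))
    }
    prior <- nrow(sub) / n
    list(mu = mu, Sigma = S, Sinv = Sinv,
         A = -0.5 * Sinv, b = as.numeric(Sinv %*% mu),
         c = -0.5 * sum(mu * (Sinv %*% mu)) - 0.5 * logdet + log(prior),
         prior = prior,
         diag_v = if (diagonal) diag(S) else NULL)
  })
  names(pars) <- as.character(classes)
  new_model("naive_bayes", classes, pars = pars, diagonal = diagonal)
}

nb_discriminants <- function(model, X) {
  d <- vapply(model$pars, function(pp) {
    q <- if (!is.null(pp$diag_v)) {
      -0.5 * as.numeric(X^2 %*% (1 / pp$diag_v))
    } else {
      rowSums((X %*% pp$A) * X)
    }
    as.numeric(q + X %*% pp$b + pp$c)
  }, numeric(nrow(X)))
  if (is.null(dim(d))) d <- matrix(d, nrow = 1)
  d
}

# ---------------------------------------------------------------------------
# LASSO (classes coded -1/+1, treated as real responses)

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

# Coordinate descent for (1/(2n))||y - b0 - X beta||^2 + lambda ||beta||_1.
lasso_cd <- function(X, y, lambda, beta = NULL, tol = 1e-8, max_iter = 10000) {
  n <- nrow(X); p <- ncol(X)
  if (is.null(beta)) beta <- numeric(p)
  xss <- colSums(X^2) / n
  b0 <- mean(y - X %*% beta)
  r <- y - b0 - as.numeric(X %*% beta)
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (j in seq_len(p)) {
      if (xss[j] == 0) next
      bj <- beta[j]
      z <- sum(X[, j] * r) / n + xss[j] * bj
      bnew <- soft_threshold(z, lambda) / xss[j]
      if (bnew != bj) {
        r <- r - X[, j] * (bnew - bj)
        delta <- max(delta, abs(bnew - bj))
        beta[j] <- bnew
      }
    }
    b0new <- b0 + mean(r)
    r <- r - (b0new - b0)
    delta <- max(delta, abs(b0new - b0))
    b0 <- b0new
    if (delta < tol) break
  }
  list(beta = beta, intercept = b0)
}

#' Train the LASSO classifier
#'
#' The two classes are coded -1/+1 and treated as real responses; the
#' coefficients minimize `(1/(2n))||y - Xbeta||^2 + lambda ||beta||_1`
#' by coordinate descent (tolerance 1e-8). `lambda` is chosen by inner
#' stratified CV (squared error, minimum-error rule) over a logarithmic
#' grid of `n_lambda` points spanning `[1e-4, 1e1] * lambda_max`,
#' `lambda_max = max|X'(y - ybar)| / n`. Score = `X beta + intercept`;
#' label = sign of score with ties to the positive class.
#'
#' @param X trials x features matrix.
#' @param labels exactly 2 classes.
#' @param n_lambda grid size (default 20).
#' @param cv_folds inner folds (default 5).
#' @param seed fold-assignment seed.
#' @param lambda fix lambda and skip the inner CV (mainly for tests).
#' @return an `eegdecode_model` with `beta`, `intercept`, `lambda`.
#' @export
train_lasso <- function(X, labels, n_lambda = 20, cv_folds = 5, seed = 0,
                        lambda = NULL) {
  classes <- check_binary(labels)
  y <- ifelse(labels == classes[2], 1, -1)
  n <- nrow(X)
  if (is.null(lambda)) {
    lam_max <- max(abs(crossprod(X, y - mean(y)))) / n
    if (lam_max == 0) lam_max <- 1e-8
    grid <- exp(seq(log(1e1 * lam_max), log(1e-4 * lam_max),
                    length.out = n_lambda))
    folds <- stratified_folds(y, cv_folds, derive_seed(seed, "lasso-cv"))
    err <- numeric(n_lambda)
    for (f in seq_len(max(folds))) {
      tr <- folds != f
      beta <- NULL
      for (li in seq_along(grid)) {
        fit <- lasso_cd(X[tr, , drop = FALSE], y[tr], grid[li], beta = beta)
        beta <- fit$beta
        pred <- as.numeric(X[!tr, , drop = FALSE] %*% fit$beta) + fit$intercept
        err[li] <- err[li] + sum((y[!tr] - pred)^2)
      }
    }
    lambda <- grid[which.min(err)]
  }
  fit <- lasso_cd(X, y, lambda)
  new_model("lasso", classes, beta = fit$beta, intercept = fit$intercept,
            lambda = lambda)
}

# ---------------------------------------------------------------------------
# Logistic regression

#' Train the logistic-regression classifier
#'
#' Maximum-likelihood fit of `P(positive | x) = 1/(1 + exp(-(w'x + b)))`
#' with a small stabilizing L2 term (1e-6, weights only) by Newton
#' iterations with step halving; converged when the penalized gradient
#' infinity-norm falls below 1e-8 (200 iterations max; on persistent
#' non-convergence the best iterate is returned with a warning). Score =
#' linear predictor.
#'
#' @param X trials x features matrix.
#' @param labels exactly 2 classes.
#' @param l2 stabilizing ridge (default 1e-6).
#' @return an `eegdecode_model` with `w`, `intercept`.
#' @export
train_logistic <- function(X, labels, l2 = 1e-6) {
  classes <- check_binary(labels)
  y <- as.numeric(labels == classes[2])
  n <- nrow(X); p <- ncol(X)
  Z <- cbind(1, X)
  theta <- numeric(p + 1)
  pen <- c(0, rep(l2, p))
  nll <- function(th) {
    eta <- as.numeric(Z %*% th)
    sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) +
      0.5 * sum(pen * th^2)
  }
  f_old <- nll(theta)
  converged <- FALSE
  for (it in seq_len(200)) {
    eta <- as.numeric(Z %*% theta)
    mu <- 1 / (1 + exp(-eta))
    g <- as.numeric(crossprod(Z, mu - y)) + pen * theta
    if (max(abs(g)) < 1e-8) { converged <- TRUE; break }
    Wd <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Z * Wd, Z) + diag(pen + 1e-12, p + 1)
    step <- tryCatch(solve(H, g), error = function(e) g / max(abs(g)))
    s <- 1
    repeat {
      thn <- theta - s * step
      fn <- nll(thn)
      if (fn <= f_old + 1e-12 || s < 1e-8) break
      s <- s / 2
    }
    theta <- thn; f_old <- fn
  }
  if (!converged) {
    warning("logistic regression did not fully converge; best iterate returned",
            call. = FALSE)
  }
  new_model("logistic", classes, w = theta[-1], intercept = theta[1],
            converged = converged)
}

# ---------------------------------------------------------------------------
# Linear soft-margin SVM (dual SMO, max-violating-pair working set)

#' Train the linear soft-margin SVM
#'
#' Solves the dual of `0.5 ||w||^2 + C sum hinge` by sequential minimal
#' optimization with maximal-violating-pair selection, stopping when the
#' KKT violation falls below 1e-6 (which bounds the duality gap at the
#' solution). Score = `w'x + b`; the margin `M = 2 / ||w||` is reported.
#'
#' @param X trials x features matrix.
#' @param labels exactly 2 classes.
#' @param C soft-margin cost (default 1).
#' @param tol KKT violation tolerance (default 1e-6).
#' @param max_iter pair-update cap (default 100 * n^2, at least 1e5).
#' @return an `eegdecode_model` with `w`, `intercept`, `margin`, `alpha`.
#' @export
train_linear_svm <- function(X, labels, C = 1, tol = 1e-6, max_iter = NULL) {
  classes <- check_binary(labels)
  y <- ifelse(labels == classes[2], 1, -1)
  n <- nrow(X)
  if (is.null(max_iter)) max_iter <- max(1e5, 100 * n^2)
  K <- tcrossprod(X)
  Q <- K * tcrossprod(y)
  alpha <- numeric(n)
  g <- rep(-1, n)                    # gradient of 0.5 a'Qa - 1'a
  it <- 0
  repeat {
    it <- it + 1
    yg <- -y * g
    up <- (y > 0 & alpha < C - 1e-12) | (y < 0 & alpha > 1e-12)
    lo <- (y < 0 & alpha < C - 1e-12) | (y > 0 & alpha > 1e-12)
    if (!any(up) || !any(lo)) break
    i <- which(up)[which.max(yg[up])]
    j <- which(lo)[which.min(yg[lo])]
    if (yg[i] - yg[j] < tol || it > max_iter) break
    # two-variable subproblem along the equality constraint:
    # alpha_i += t*y_i, alpha_j -= t*y_j with t >= 0
    quad <- max(Q[i, i] + Q[j, j] - 2 * y[i] * y[j] * Q[i, j], 1e-12)
    t_step <- (yg[i] - yg[j]) / quad
    bound_i <- if (y[i] > 0) C - alpha[i] else alpha[i]
    bound_j <- if (y[j] > 0) alpha[j] else C - alpha[j]
    t_step <- min(t_step, bound_i, bound_j)
    alpha[i] <- alpha[i] + t_step * y[i]
    alpha[j] <- alpha[j] - t_step * y[j]
    g <- g + t_step * (y * (K[, i] - K[, j]))
  }
  if (it > max_iter) {
    warning("SVM solver hit the iteration cap before reaching tolerance",
            call. = FALSE)
  }
  w <- as.numeric(crossprod(X, alpha * y))
  sv <- alpha > 1e-8 & alpha < C - 1e-8
  b <- if (any(sv)) {
    mean(y[sv] - as.numeric(X[sv, , drop = FALSE] %*% w))
  } else {
    yg <- -y * g
    up <- (y > 0 & alpha < C - 1e-12) | (y < 0 & alpha > 1e-12)
    lo <- (y < 0 & alpha < C - 1e-12) | (y > 0 & alpha > 1e-12)
    m_up <- if (any(up)) max(yg[up]) else 0
    m_lo <- if (any(lo)) min(yg[lo]) else 0
    (m_up + m_lo) / 2
  }
  nw <- sqrt(sum(w^2))
  new_model("linear_svm", classes, w = w, intercept = b,
            margin = if (nw > 0) 2 / nw else Inf, alpha = alpha, C = C)
}

# ---------------------------------------------------------------------------
# Unified prediction

#' Predict labels and scores
#'
#' Returns deterministic labels and real-valued scores; for binary models
#' a higher score means stronger evidence for the positive (second
#' sorted) class, with ties at 0 resolved toward it. Multiclass naive
#' Bayes returns the discriminant matrix as `scores`.
#'
#' @param object an `eegdecode_model`.
#' @param X trials x features matrix (columns must match training).
#' @param ... unused.
#' @return list with `labels` and `scores`.
#' @export
predict.eegdecode_model <- function(object, X, ...) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  p_expected <- switch(object$kind,
    naive_bayes = length(object$pars[[1]]$mu),
    lasso = length(object$beta),
    logistic = length(object$w),
    linear_svm = length(object$w))
  abort_if(ncol(X) != p_expected,
           "feature count mismatch: model has %d, data has %d",
           p_expected, ncol(X))
  if (object$kind == "naive_bayes") {
    d <- nb_discriminants(object, X)
    if (length(object$classes) == 2) {
      score <- d[, 2] - d[, 1]
      labels <- object$classes[ifelse(score >= 0, 2, 1)]
      return(list(labels = labels, scores = as.numeric(score)))
    }
    labels <- object$classes[max.col(d, ties.method = "first")]
    return(list(labels = labels, scores = d))
  }
  score <- switch(object$kind,
    lasso = as.numeric(X %*% object$beta) + object$intercept,
    logistic = as.numeric(X %*% object$w) + object$intercept,
    linear_svm = as.numeric(X %*% object$w) + object$intercept)
  labels <- object$classes[ifelse(score >= 0, 2, 1)]
  list(labels = labels, scores = score)
}

#' Serialize a trained model to JSON
#' @param model an `eegdecode_model`.
#' @param path output file.
#' @export
write_model <- function(model, path) {
  obj <- list(kind = model$kind, classes = model$classes)
  extras <- switch(model$kind,
    naive_bayes = list(pars = lapply(model$pars, function(pp)
      list(mu = pp$mu, Sigma = pp$Sigma, prior = pp$prior))),
    lasso = list(beta = model$beta, intercept = model$intercept,
                 lambda = model$lambda),
    logistic = list(w = model$w, intercept = model$intercept),
    linear_svm = list(w = model$w, intercept = model$intercept,
                      margin = model$margin, C = model$C))
  jsonlite::write_json(c(obj, extras), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
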