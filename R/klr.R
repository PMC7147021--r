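#' Kernel specification
#'
#' Three kernel families over one-of-n encoded windows: the linear kernel
#' `K(x, x') = x . x'` (for binary window vectors, the number of window
#' positions at which the two windows agree); the polynomial kernel
#' `K(x, x') = (x . x' + c)^d` with degree `d` fixed at 2 (quadratic) or
#' 3 (cubic) and offset hyper-parameter `c >= 0`; and the radial basis
#' function kernel `K(x, x') = exp(-theta ||x - x'||^2)` with sensitivity
#' `theta > 0`.
#'
#' @param family `"linear"`, `"polynomial"` or `"rbf"`.
#' @param d Polynomial degree, 2 or 3.
#' @param c Polynomial offset, non-negative.
#' @param theta RBF sensitivity, positive.
#' @return An object of class `"kernel_spec"`.
#' @export
kernel_spec <- function(family = c("linear", "polynomial", "rbf"),
                        d = 2L, c = 1, theta = 0.01) {
  family <- match.arg(family)
  if (family == "polynomial") {
    if (!d %in% c(2L, 3L)) stop("polynomial degree d must be 2 or 3")
    if (c < 0) stop("polynomial offset c must be >= 0")
  }
  if (family == "rbf" && theta <= 0) stop("rbf theta must be > 0")
  structure(list(family = family, d = as.integer(d), c = c, theta = theta),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  extra <- switch(x$family,
                  linear = "",
                  polynomial = sprintf(" (d = %d, c = %g)", x$d, x$c),
                  rbf = sprintf(" (theta = %g)", x$theta))
  cat("<kernel_spec> ", x$family, extra, "\n", sep = "")
  invisible(x)
}

#' Evaluate a kernel on a pair of vectors
#'
#' @param spec A [kernel_spec()].
#' @param x,x2 Numeric vectors of equal dimension.
#' @return The scalar kernel value; symmetric in its arguments.
#' @export
kernel_eval <- function(spec, x, x2) {
  if (length(x) != length(x2)) stop("dimension mismatch")
  x <- as.numeric(x); x2 <- as.numeric(x2)
  switch(spec$family,
         linear = sum(x * x2),
         polynomial = (sum(x * x2) + spec$c)^spec$d,
         rbf = exp(-spec$theta * sum((x - x2)^2)))
}

#' Kernel (Gram) matrix
#'
#' Computes the kernel matrix between the rows of `X` and the rows of
#' `X2` (or `X` itself). For any set of inputs the self-Gram matrix is
#' symmetric positive semi-definite up to numerical tolerance.
#'
#' @param spec A [kernel_spec()].
#' @param X Input matrix (dense or sparse), one example per row.
#' @param X2 Optional second input matrix; default `X`.
#' @return Dense numeric matrix of kernel values, `nrow(X) x nrow(X2)`.
#' @export
gram_matrix <- function(spec, X, X2 = NULL) {
  dots <- if (is.null(X2)) Matrix::tcrossprod(X) else
    Matrix::tcrossprod(X, X2)
  dots <- as.matrix(dots)
  switch(spec$family,
         linear = dots,
         polynomial = (dots + spec$c)^spec$d,
         rbf = {
           sq1 <- Matrix::rowSums(X^2)
           sq2 <- if (is.null(X2)) sq1 else Matrix::rowSums(X2^2)
           d2 <- outer(sq1, sq2, "+") - 2 * dots
           d2[d2 < 0] <- 0
           exp(-spec$theta * d2)
         })
}

#' Training configuration for kernel logistic regression
#'
#' @param gamma Data-fit weight `gamma > 0` of the regularised
#'   cross-entropy objective; larger values mean weaker regularisation.
#' @param max_irls_iterations Iteration cap for IRLS.
#' @param convergence_tol Relative change in the penalised objective below
#'   which IRLS is declared converged.
#' @param seed Integer seed recorded for provenance (training itself is
#'   deterministic).
#' @param compute_loo Also compute the approximate leave-one-out loss as a
#'   by-product of training (an extra matrix inversion); disable when the
#'   estimate is not needed.
#' @return An object of class `"training_config"`.
#' @export
training_config <- function(gamma = 1, max_irls_iterations = 100L,
                            convergence_tol = 1e-8, seed = 1L,
                            compute_loo = TRUE) {
  stopifnot(gamma > 0, convergence_tol > 0, max_irls_iterations >= 1)
  structure(list(gamma = gamma,
                 max_irls_iterations = as.integer(max_irls_iterations),
                 convergence_tol = convergence_tol,
                 seed = as.integer(seed),
                 compute_loo = isTRUE(compute_loo)),
            class = "training_config")
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(eta) 1 / (1 + exp(-eta))

clip01 <- function(y, eps = 1e-12) pmin(pmax(y, eps), 1 - eps)

# Regularised cross-entropy objective in the dual:
# E = 1/2 a' K a - (gamma/2) * sum[t log y + (1 - t) log(1 - y)]
klr_objective <- function(K, alpha, b, t, gamma) {
  eta <- drop(K %*% alpha) + b
  y <- clip01(inv_logit(eta))
  0.5 * sum(alpha * drop(K %*% alpha)) -
    (gamma / 2) * sum(t * log(y) + (1 - t) * log(1 - y))
}

#' Train a kernel logistic regression model
#'
#' Fits the dual-form KLR model `logit y(x) = sum_i alpha_i K(x_i, x) + b`
#' by minimising the regularised cross-entropy objective
#' `E = 1/2 ||w||^2 - (gamma/2) sum_i [t_i log y_i + (1 - t_i) log(1 - y_i)]`
#' with `||w||^2 = alpha' K alpha`. Optimisation is iteratively reweighted
#' least squares in the dual: each iteration solves the weighted
#' kernel-ridge system
#' `[K + lambda S^-1, 1; 1', 0] [alpha; b] = [z; 0]`
#' with `lambda = 2/gamma`, IRLS weights `s_i = y_i (1 - y_i)` and working
#' responses `z_i = eta_i + (t_i - y_i)/s_i`. A step-halving line search
#' guarantees the objective never increases; initialisation is `alpha = 0`,
#' `b = logit(mean(t))`. A jitter of `1e-10 * trace(K) / l` is added to the
#' system diagonal for numerical stability. Training is deterministic.
#'
#' @param train A `"windowed_examples"`/`"training_set"` object with both
#'   classes present, or a list with elements `X` (matrix) and `t`.
#' @param spec A [kernel_spec()].
#' @param cfg A [training_config()].
#' @return An object of class `"klr_model"`: kernel spec, dual
#'   coefficients `alpha`, bias `b`, retained training inputs `X_train`,
#'   `gamma`, `converged` flag, the achieved objective `objective` and the
#'   approximate leave-one-out cross-entropy `loo_loss`.
#' @export
train_klr <- function(train, spec, cfg = training_config()) {
  X <- train$X
  t <- as.numeric(train$t)
  if (length(unique(t)) < 2L) {
    stop("training set must contain both classes")
  }
  ell <- nrow(X)
  K <- gram_matrix(spec, X)
  lambda <- 2 / cfg$gamma
  jitter <- 1e-10 * sum(diag(K)) / ell

  alpha <- rep(0, ell)
  b <- logit(clip01(mean(t)))
  E <- klr_objective(K, alpha, b, t, cfg$gamma)
  converged <- FALSE
  S_final <- NULL
  z_final <- NULL

  for (iter in seq_len(cfg$max_irls_iterations)) {
    eta <- drop(K %*% alpha) + b
    y <- clip01(inv_logit(eta))
    s <- pmax(y * (1 - y), 1e-10)
    z <- eta + (t - y) / s
    M <- rbind(cbind(K + diag(lambda / s + jitter, ell), 1),
               c(rep(1, ell), 0))
    sol <- solve(M, c(z, 0))
    alpha_new <- sol[seq_len(ell)]
    b_new <- sol[ell + 1L]
    # step-halving line search on the objective
    step <- 1
    repeat {
      a_try <- alpha + step * (alpha_new - alpha)
      b_try <- b + step * (b_new - b)
      E_try <- klr_objective(K, a_try, b_try, t, cfg$gamma)
      if (E_try <= E || step < 1e-8) break
      step <- step / 2
    }
    rel <- abs(E - E_try) / max(abs(E), 1e-12)
    alpha <- a_try
    b <- b_try
    E <- E_try
    S_final <- s
    z_final <- z
    if (rel < cfg$convergence_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("IRLS did not converge in ", cfg$max_irls_iterations,
            " iterations (relative change ", format(rel), ")")
  }

  model <- structure(list(kernel = spec, alpha = alpha, b = b,
                          X_train = X, gamma = cfg$gamma,
                          w = if (!is.null(train$w)) train$w else NA_integer_,
                          converged = converged, objective = E,
                          loo_loss = NA_real_),
                     class = "klr_model")
  if (!identical(cfg$compute_loo, FALSE)) {
    model$loo_loss <- tryCatch(
      approx_loo_from_fit(K, model, t, lambda, jitter),
      error = function(e) NA_real_)
  }
  model
}

#' @export
print.klr_model <- function(x, ...) {
  cat("<klr_model> ", x$kernel$family, " kernel, l = ", length(x$alpha),
      ", gamma = ", format(x$gamma), ", approx LOO loss = ",
      format(x$loo_loss, digits = 4),
      if (!x$converged) " [NOT CONVERGED]" else "", "\n", sep = "")
  invisible(x)
}

# Leverage-based approximate leave-one-out cross-entropy from the final
# IRLS system: with M the bordered system matrix, the left-out linear
# predictor is eta_i^(-i) = z_i - alpha_i / (M^-1)_ii, i.e. the predicted
# residual of the weighted ridge system scaled by the inverse leverage.
approx_loo_from_fit <- function(K, model, t, lambda, jitter) {
  ell <- length(model$alpha)
  eta <- drop(K %*% model$alpha) + model$b
  y <- clip01(inv_logit(eta))
  s <- pmax(y * (1 - y), 1e-10)
  z <- eta + (t - y) / s
  M <- rbind(cbind(K + diag(lambda / s + jitter, ell), 1),
             c(rep(1, ell), 0))
  Minv <- tryCatch(solve(M), error = function(e)
    stop("numerically singular IRLS system; increase regularisation ",
         "(smaller gamma)"))
  dMi <- diag(Minv)[seq_len(ell)]
  eta_loo <- z - model$alpha / dMi
  y_loo <- clip01(inv_logit(eta_loo))
  -mean(t * log(y_loo) + (1 - t) * log(1 - y_loo))
}

#' Approximate leave-one-out cross-entropy loss
#'
#' Trains the model and returns a closed-form leverage-based
#' approximation to the leave-one-out cross-validated cross-entropy,
#' computed from the final IRLS weighted system (hat-matrix diagonal).
#' This is a cheap by-product of training used as the tuning objective.
#'
#' @inheritParams train_klr
#' @return Mean leave-one-out cross-entropy estimate (non-negative).
#' @export
approx_loo_loss <- function(train, spec, cfg = training_config()) {
  model <- train_klr(train, spec, cfg)
  if (!is.finite(model$loo_loss)) {
    stop("numerically singular IRLS system; increase regularisation ",
         "(smaller gamma)")
  }
  model$loo_loss
}

#' Predict hinge probabilities from a KLR model
#'
#' Evaluates `y(x) = logit^-1( sum_i alpha_i K(x_i, x) + b )`, the
#' a-posteriori probability that the central residue of each window is in
#' a hinge-bending region.
#'
#' @param object A `"klr_model"`.
#' @param newdata Matrix of encoded windows (one per row), a
#'   `"windowed_examples"` object, or a single vector.
#' @param ... Unused.
#' @return Numeric vector of probabilities in `(0, 1)`.
#' @export
predict.klr_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "windowed_examples")) newdata$X else newdata
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != ncol(object$X_train)) stop("dimension mismatch")
  Kx <- gram_matrix(object$kernel, X, object$X_train)
  inv_logit(drop(Kx %*% object$alpha) + object$b)
}

#' Threshold a predicted probability into a class call
#'
#' A residue is called part of a hinge-bending region iff its predicted
#' probability is strictly above the threshold.
#'
#' @param p Probabilities.
#' @param threshold Decision threshold in `(0, 1)`.
#' @return Character vector over `{"hinge", "non-hinge"}`.
#' @export
classify <- function(p, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  ifelse(p > threshold, "hinge", "non-hinge")
}

#' Tune KLR hyper-parameters by Nelder-Mead on approximate LOO loss
#'
#' Minimises the approximate leave-one-out cross-entropy over the
#' family-appropriate hyper-parameters: `log gamma` always, plus `log c`
#' for polynomial kernels and `log theta` for the RBF kernel (the
#' polynomial degree stays fixed). The search runs in natural-log space
#' with the Nelder-Mead simplex (standard coefficients, relative
#' function-value tolerance 1e-4, at most 200 evaluations) and is
#' deterministic given the starting point. Tuning uses the training set
#' only.
#'
#' @param train Training set (see [train_klr()]).
#' @param family Kernel family to tune.
#' @param init Named list of starting values; recognised names `gamma`,
#'   `c`, `theta`. Defaults: `gamma = 1`, `c = 1`, `theta = 0.01`.
#' @param d Polynomial degree (fixed during tuning).
#' @param max_eval Evaluation cap; default 200.
#' @return List with elements `spec` (tuned [kernel_spec()]), `cfg`
#'   (tuned [training_config()]) and `loo_loss` (value at the optimum).
#' @export
tune_hyperparams <- function(train,
                             family = c("linear", "polynomial", "rbf"),
                             init = list(), d = 2L, max_eval = 200L) {
  family <- match.arg(family)
  defaults <- list(gamma = 1, c = 1, theta = 0.01)
  init <- utils::modifyList(defaults, init)
  par_names <- switch(family,
                      linear = "gamma",
                      polynomial = c("gamma", "c"),
                      rbf = c("gamma", "theta"))
  par0 <- log(unlist(init[par_names]))
  n_bad <- 0L

  build <- function(logpar) {
    p <- as.list(exp(logpar))
    names(p) <- par_names
    spec <- switch(family,
      linear = kernel_spec("linear"),
      polynomial = kernel_spec("polynomial", d = d, c = p$c),
      rbf = kernel_spec("rbf", theta = p$theta))
    list(spec = spec, cfg = training_config(gamma = p$gamma))
  }
  objective <- function(logpar) {
    sp <- build(logpar)
    val <- tryCatch(
      suppressWarnings(approx_loo_loss(train, sp$spec, sp$cfg)),
      error = function(e) NA_real_)
    if (!is.finite(val)) {
      n_bad <<- n_bad + 1L
      return(1e10)
    }
    val
  }

  opt <- if (length(par0) == 1L) {
    suppressWarnings(stats::optim(par0, objective, method = "Nelder-Mead",
                                  control = list(maxit = max_eval,
                                                 reltol = 1e-4)))
  } else {
    stats::optim(par0, objective, method = "Nelder-Mead",
                 control = list(maxit = max_eval, reltol = 1e-4))
  }
  if (opt$value >= 1e10) stop("all hyper-parameter evaluations failed")
  sp <- build(opt$par)
  list(spec = sp$spec, cfg = sp$cfg, loo_loss = opt$value)
}

#' Explicit feature map of the quadratic kernel
#'
#' Returns the explicit vector `phi(x)` whose inner products reproduce the
#' quadratic kernel exactly: `phi(x) . phi(x') = (x . x' + c)^2`. The
#' component layout is all pairwise products `sqrt(2) x_i x_j` for
#' `i < j`, then the squares `x_i^2`, then the scaled linear terms
#' `sqrt(2 c) x_i`, then the constant `c`.
#'
#' @param x Numeric vector.
#' @param c Kernel offset, non-negative.
#' @return Numeric vector of length `choose(n, 2) + 2 n + 1` where
#'   `n = length(x)`.
#' @export
quadratic_feature_map <- function(x, c = 1) {
  stopifnot(c >= 0)
  x <- as.numeric(x)
  n <- length(x)
  xx <- tcrossprod(x)
  pairs <- sqrt(2) * xx[upper.tri(xx)]
  c(pairs, x^2, sqrt(2 * c) * x, c)
}
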