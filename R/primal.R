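#' Convert a dual KLR model to primal form
#'
#' The primal weights are recovered from the dual coefficients via
#' `w = sum_i alpha_i phi(x_i)`, which is tractable for the finite feature
#' spaces of the linear and quadratic kernels. For the quadratic kernel
#' the model is stored as an equivalent quadratic form: the logit of a new
#' window `x` is `x' Q x + lin . x + b0` with
#' `Q = sum_i alpha_i x_i x_i'`, `lin = 2 c sum_i alpha_i x_i` and
#' `b0 = c^2 sum_i alpha_i + b`. This reproduces the dual prediction
#' exactly and makes component-wise ensemble averaging well defined even
#' across members tuned to different kernel offsets. The explicit
#' feature-space weight vector of [quadratic_feature_map()] is available
#' via [primal_phi_weights()].
#'
#' @param model A `"klr_model"` with linear or quadratic (degree-2
#'   polynomial) kernel. Cubic and RBF models have no tractable primal
#'   form here and are rejected.
#' @return An object of class `"primal_model"` with fields `family`
#'   (`"linear"` or `"quadratic"`), `dim`, `lin`, `b0`, and for quadratic
#'   models `Q`, plus provenance fields `w` (window length), `c`, `q`,
#'   `sum_alpha`.
#' @export
primal_model <- function(model) {
  stopifnot(inherits(model, "klr_model"))
  fam <- model$kernel$family
  if (fam == "rbf" || (fam == "polynomial" && model$kernel$d != 2L)) {
    stop("primal weights are only available for linear and quadratic ",
         "kernels")
  }
  X <- model$X_train
  a <- model$alpha
  q <- as.numeric(Matrix::crossprod(X, a))
  if (fam == "linear") {
    new_primal_model(family = "linear", dim = ncol(X), Q = NULL,
                     lin = q, b0 = model$b, w = model$w,
                     c = NA_real_, q = q, sum_alpha = sum(a))
  } else {
    cc <- model$kernel$c
    Q <- as.matrix(Matrix::crossprod(X, X * a))
    Q <- (Q + t(Q)) / 2  # symmetrise against round-off
    new_primal_model(family = "quadratic", dim = ncol(X), Q = Q,
                     lin = 2 * cc * q, b0 = cc^2 * sum(a) + model$b,
                     w = model$w, c = cc, q = q, sum_alpha = sum(a))
  }
}

new_primal_model <- function(family, dim, Q, lin, b0, w, c, q, sum_alpha) {
  structure(list(family = family, dim = dim, Q = Q, lin = lin, b0 = b0,
                 w = w, c = c, q = q, sum_alpha = sum_alpha),
            class = "primal_model")
}

#' @export
print.primal_model <- function(x, ...) {
  cat("<primal_model> ", x$family, ", dim = ", x$dim,
      if (!is.na(x$w)) paste0(" (window ", x$w, ")"), "\n", sep = "")
  invisible(x)
}

#' Predict from a primal model
#'
#' @param object A `"primal_model"`.
#' @param newdata Encoded window matrix, `"windowed_examples"` object or
#'   single vector.
#' @param ... Unused.
#' @return Probabilities; identical to the dual-form prediction of the
#'   source model to within round-off.
#' @export
predict.primal_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "windowed_examples")) newdata$X else newdata
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != object$dim) stop("dimension mismatch")
  eta <- as.numeric(X %*% object$lin) + object$b0
  if (object$family == "quadratic") {
    XQ <- as.matrix(X %*% object$Q)
    eta <- eta + Matrix::rowSums(XQ * X)
  }
  inv_logit(eta)
}

#' Explicit feature-space weight vector
#'
#' Materialises `w = sum_i alpha_i phi(x_i)` in the component layout of
#' [quadratic_feature_map()] (or the identity map for linear models).
#' Intended for small windows; the quadratic vector has
#' `choose(24 w, 2) + 48 w + 1` components.
#'
#' @param pm A `"primal_model"`.
#' @return Numeric weight vector.
#' @export
primal_phi_weights <- function(pm) {
  if (pm$family == "linear") return(pm$lin)
  Q <- pm$Q
  # for i < j the phi component is sqrt(2) x_i x_j, so its weight is
  # sqrt(2) * sum_k alpha_k x_ki x_kj = sqrt(2) * Q_ij
  pairs <- sqrt(2) * Q[upper.tri(Q)]
  c(pairs, diag(Q), sqrt(2 * pm$c) * pm$q, pm$c * pm$sum_alpha)
}

# effective per-indicator linear weight on binary inputs: the squared and
# scaled-linear phi components of a one-hot indicator collapse onto the
# indicator itself (x^2 = x), so they fold into one reportable weight
effective_linear_weights <- function(pm) {
  if (pm$family == "linear") pm$lin else diag(pm$Q) + pm$lin
}

# effective pair weight (i != j): logit contribution when both indicators
# are active, i.e. 2 Q_ij for quadratic models
effective_pair_weight_matrix <- function(pm) {
  if (pm$family != "quadratic") stop("pair weights need a quadratic model")
  2 * pm$Q
}
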