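SERIAL_FORMAT <- "hingeseek-model/1"

klr_model_to_list <- function(model) {
  X <- model$X_train
  # sparse storage: per training window, the 1-based active column indices
  Xt <- as(as(X, "TsparseMatrix"), "generalMatrix")
  act <- split(Xt@j + 1L, Xt@i + 1L)
  act <- lapply(act, sort)
  list(kernel = list(family = model$kernel$family, d = model$kernel$d,
                     c = model$kernel$c, theta = model$kernel$theta),
       gamma = model$gamma, alpha = model$alpha, b = model$b,
       w = model$w, dim = ncol(X), converged = model$converged,
       loo_loss = model$loo_loss, active_columns = unname(act))
}

klr_model_from_list <- function(x) {
  rows <- rep(seq_along(x$active_columns),
              lengths(x$active_columns))
  X <- Matrix::sparseMatrix(i = rows, j = unlist(x$active_columns),
                            x = 1, dims = c(length(x$active_columns),
                                            x$dim))
  spec <- kernel_spec(x$kernel$family, d = x$kernel$d, c = x$kernel$c,
                      theta = x$kernel$theta)
  structure(list(kernel = spec, alpha = as.numeric(x$alpha), b = x$b,
                 X_train = X, gamma = x$gamma,
                 w = if (is.null(x$w)) NA_integer_ else x$w,
                 converged = isTRUE(x$converged),
                 objective = NA_real_,
                 loo_loss = if (is.null(x$loo_loss)) NA_real_ else
                   x$loo_loss),
            class = "klr_model")
}

#' Serialise a KLR model to JSON
#'
#' Flat, versioned JSON container holding the kernel specification,
#' regularisation, dual coefficients, bias, and the training windows as
#' sparse active-column index lists.
#'
#' @param model A `"klr_model"`.
#' @param path Output path.
#' @param provenance Optional named list (seed, dataset hash, ...)
#'   stored verbatim.
#' @export
write_klr_model <- function(model, path, provenance = list()) {
  payload <- c(list(format = SERIAL_FORMAT, type = "klr_model",
                    provenance = provenance),
               klr_model_to_list(model))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_klr_model
#' @return `read_klr_model` returns the reconstructed `"klr_model"`;
#'   predictions round-trip exactly.
#' @export
read_klr_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(x$format, SERIAL_FORMAT) ||
      !identical(x$type, "klr_model")) {
    stop("not a serialised KLR model: ", path)
  }
  klr_model_from_list(normalise_model_fields(x))
}

normalise_model_fields <- function(x) {
  x$alpha <- as.numeric(unlist(x$alpha))
  x$active_columns <- lapply(x$active_columns,
                             function(a) as.integer(unlist(a)))
  x$kernel <- lapply(x$kernel, function(v) if (is.null(v)) NULL else
    unlist(v))
  x$b <- as.numeric(x$b)
  x$gamma <- as.numeric(x$gamma)
  x$dim <- as.integer(x$dim)
  x
}

#' Serialise a bootstrap ensemble to JSON
#'
#' Members are stored in dual form (compact); primal weights are
#' rebuilt on demand by [aggregate_ensemble()].
#'
#' @param ens A `"hinge_ensemble"`.
#' @param path Output path.
#' @param provenance Optional named list stored verbatim.
#' @export
write_ensemble <- function(ens, path, provenance = list()) {
  payload <- list(format = SERIAL_FORMAT, type = "hinge_ensemble",
                  provenance = provenance,
                  w = ens$w, family = ens$family,
                  n_members = ens$n_members,
                  members = lapply(ens$members, function(m) {
                    c(list(train_ids = m$train_ids, seed = m$seed),
                      klr_model_to_list(m$model))
                  }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(x$format, SERIAL_FORMAT) ||
      !identical(x$type, "hinge_ensemble")) {
    stop("not a serialised ensemble: ", path)
  }
  members <- lapply(x$members, function(m) {
    m <- normalise_model_fields(m)
    list(model = klr_model_from_list(m),
         train_ids = as.character(unlist(m$train_ids)),
         seed = as.integer(m$seed))
  })
  structure(list(members = members, w = as.integer(x$w),
                 family = x$family, n_members = length(members)),
            class = "hinge_ensemble")
}
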