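# map (window position p in 1..w, amino acid index a0 in 0..23) to the
# encoded column index
indicator_index <- function(p, a0) (p - 1L) * 24L + a0 + 1L

window_offsets <- function(w) seq.int(-(w - 1L) %/% 2L, (w - 1L) %/% 2L)

#' Per-position weight profile of an amino acid
#'
#' Extracts, for one amino acid, the model weight applied at every window
#' offset (0 = central residue). For linear models these are the primal
#' weights directly; for quadratic models the squared and scaled-linear
#' feature components are folded into a single effective weight per
#' position (exact for one-hot inputs, where `x^2 = x`). Optional
#' normalisation divides by the largest weight magnitude in the profile,
#' expressing each weight as a proportion of the strongest weight the
#' model applies to that amino acid.
#'
#' @param pm A `"primal_model"` (linear or quadratic).
#' @param aa Single residue character.
#' @param normalise Normalise by max absolute weight.
#' @return An object of class `"weight_profile"`: data frame with columns
#'   `offset` and `weight` (and `normalised_weight` if requested).
#' @export
linear_profile <- function(pm, aa, normalise = FALSE) {
  stopifnot(inherits(pm, "primal_model"))
  a0 <- alphabet_index(aa)
  w <- pm$dim %/% 24L
  lw <- effective_linear_weights(pm)
  idx <- indicator_index(seq_len(w), a0)
  out <- data.frame(offset = window_offsets(w), weight = lw[idx])
  if (normalise) {
    m <- max(abs(out$weight))
    out$normalised_weight <- if (m > 0) out$weight / m else out$weight
  }
  structure(out, class = c("weight_profile", "data.frame"),
            aa = aa, normalised = normalise)
}

#' Pairwise product-term heatmap
#'
#' For a quadratic model, the `w x w` matrix whose `(i, j)` entry is the
#' effective logit contribution of the product term for `aa1` at window
#' offset `i` and `aa2` at offset `j` when both indicators are active
#' (the feature map's `sqrt(2)` scaling is folded back in). For
#' `aa1 == aa2` the matrix is symmetric; its diagonal carries the folded
#' squared-term weight.
#'
#' @param pm A quadratic `"primal_model"`.
#' @param aa1,aa2 Residue characters.
#' @return An object of class `"pair_heatmap"`: the matrix with offsets as
#'   dimnames (rows = `aa1` position, columns = `aa2` position).
#' @export
pair_heatmap <- function(pm, aa1, aa2) {
  stopifnot(inherits(pm, "primal_model"))
  if (pm$family != "quadratic") {
    stop("pair heatmaps require a quadratic model")
  }
  a1 <- alphabet_index(aa1)
  a2 <- alphabet_index(aa2)
  w <- pm$dim %/% 24L
  P <- effective_pair_weight_matrix(pm)
  idx1 <- indicator_index(seq_len(w), a1)
  idx2 <- indicator_index(seq_len(w), a2)
  m <- P[idx1, idx2, drop = FALSE]
  if (a1 == a2) diag(m) <- diag(pm$Q)[idx1]
  offs <- window_offsets(w)
  dimnames(m) <- list(offs, offs)
  structure(m, class = c("pair_heatmap", class(m)),
            aa1 = aa1, aa2 = aa2)
}

#' Strongest product-term weights of a quadratic model
#'
#' Ranks all indicator pairs `(position, amino acid) x (position, amino
#' acid)` by absolute effective product weight. Ties are broken
#' deterministically by `(aa1, aa2, pos1, pos2)` lexicographic order.
#'
#' @param pm A quadratic `"primal_model"`.
#' @param top_k Number of pairs to return (positive); capped at the
#'   number of distinct pairs.
#' @return Data frame `(aa1, offset1, aa2, offset2, weight)` in
#'   decreasing order of `|weight|`.
#' @export
strongest_pairs <- function(pm, top_k) {
  stopifnot(inherits(pm, "primal_model"))
  if (pm$family != "quadratic") stop("requires a quadratic model")
  if (top_k <= 0) stop("top_k must be positive")
  P <- effective_pair_weight_matrix(pm)
  n <- pm$dim
  ut <- which(upper.tri(P), arr.ind = TRUE)
  w <- pm$dim %/% 24L
  offs <- window_offsets(w)
  pos1 <- (ut[, 1] - 1L) %/% 24L + 1L
  aa1 <- ENCODING_ALPHABET[(ut[, 1] - 1L) %% 24L + 1L]
  pos2 <- (ut[, 2] - 1L) %/% 24L + 1L
  aa2 <- ENCODING_ALPHABET[(ut[, 2] - 1L) %% 24L + 1L]
  df <- data.frame(aa1 = aa1, offset1 = offs[pos1],
                   aa2 = aa2, offset2 = offs[pos2],
                   weight = P[upper.tri(P)])
  ord <- order(-abs(df$weight), df$aa1, df$aa2, df$offset1, df$offset2)
  utils::head(df[ord, ], min(top_k, nrow(df)))
}

#' Write a weight profile as TSV
#'
#' Columns `amino_acid`, `offset`, `weight`, `normalised_weight`.
#'
#' @param profile A `"weight_profile"`.
#' @param path Output path.
#' @export
write_profile <- function(profile, path) {
  m <- max(abs(profile$weight))
  df <- data.frame(amino_acid = attr(profile, "aa"),
                   offset = profile$offset, weight = profile$weight,
                   normalised_weight = if (m > 0) profile$weight / m else
                     profile$weight)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a pair heatmap as TSV
#'
#' Long-format columns `aa1`, `aa2`, `offset1`, `offset2`, `weight`.
#'
#' @param hm A `"pair_heatmap"`.
#' @param path Output path.
#' @export
write_heatmap <- function(hm, path) {
  offs <- as.integer(rownames(hm))
  df <- expand.grid(offset1 = offs, offset2 = offs)
  df$aa1 <- attr(hm, "aa1")
  df$aa2 <- attr(hm, "aa2")
  df$weight <- as.vector(unclass(hm))
  utils::write.table(df[, c("aa1", "aa2", "offset1", "offset2", "weight")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot an amino acid's positional weight profile
#'
#' @param profile A `"weight_profile"` from [linear_profile()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot_profile <- function(profile, ...) {
  graphics::plot(profile$offset, profile$weight, type = "l",
                 xlab = "window offset", ylab = "weight",
                 main = paste("Positional weights:", attr(profile, "aa")),
                 ...)
  graphics::abline(h = 0, lty = 2)
  graphics::abline(v = 0, lty = 3)
  invisible(profile)
}

#' Plot a product-term weight heatmap
#'
#' @param hm A `"pair_heatmap"` from [pair_heatmap()].
#' @param ... Passed to [graphics::image()].
#' @export
plot_heatmap <- function(hm, ...) {
  offs <- as.integer(rownames(hm))
  lim <- max(abs(hm))
  pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(64)
  graphics::image(offs, offs, unclass(hm), col = pal,
                  zlim = c(-lim, lim),
                  xlab = paste(attr(hm, "aa1"), "offset"),
                  ylab = paste(attr(hm, "aa2"), "offset"),
                  main = paste("Product-term weights:",
                               attr(hm, "aa1"), "x", attr(hm, "aa2")),
                  ...)
  invisible(hm)
}
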