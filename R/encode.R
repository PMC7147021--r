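# 24-letter encoding alphabet: the 20 standard amino acids in alphabetical
# order, the ambiguity codes B, X, Z, and '-' as the beyond-terminus dummy.
ENCODING_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                       "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y",
                       "B", "X", "Z", "-")

# residues that may appear inside a sequence (everything but '-')
RESIDUE_ALPHABET <- ENCODING_ALPHABET[-24L]

#' The residue encoding alphabet
#'
#' @return Character vector of the 24 encoding characters, in index order:
#'   the 20 standard amino acids alphabetically, then `B`, `X`, `Z`, `-`.
#' @export
residue_alphabet <- function() ENCODING_ALPHABET

#' Map residue characters to encoding indices
#'
#' The one-of-n encoding assigns each window position a block of 24
#' indicator components, one per alphabet character. The mapping is fixed:
#' `A` is 0, the standard amino acids follow alphabetically, then `B` (20),
#' `X` (21), `Z` (22) and the terminus dummy `-` (23).
#'
#' @param ch Character vector of single characters.
#' @return Integer vector of 0-based indices in `[0, 24)`.
#' @examples
#' alphabet_index(c("A", "-"))  # 0 23
#' @export
alphabet_index <- function(ch) {
  idx <- match(ch, ENCODING_ALPHABET)
  if (anyNA(idx)) {
    stop("unknown residue character '", ch[which(is.na(idx))[1L]], "'")
  }
  idx - 1L
}

#' Sliding-window configuration
#'
#' Windows must have odd length so that a central residue exists to carry
#' the class label. Lengths above 101 are allowed with a warning; the
#' useful range in practice is 1 to 101.
#'
#' @param w Window length in residues (odd, at least 1).
#' @return An object of class `"window_config"`.
#' @export
window_config <- function(w) {
  stopifnot(length(w) == 1L, is.numeric(w), w == as.integer(w))
  w <- as.integer(w)
  if (w < 1L) stop("window length must be at least 1")
  if (w %% 2L == 0L) {
    stop("window length must be odd: a central residue is required to ",
         "carry the label")
  }
  if (w > 101L) warning("window length ", w, " exceeds the explored range")
  structure(list(w = w), class = "window_config")
}

# Sparse one-of-n encoding of all length-w windows over a residue string.
# Row i corresponds to the window centred on residue i; positions beyond
# either terminus take the '-' dummy. Returns an L x 24w dgCMatrix.
encode_windows <- function(residues, w) {
  ch <- strsplit(residues, "", fixed = TRUE)[[1]]
  L <- length(ch)
  if (L == 0L) stop("empty sequence")
  idx0 <- alphabet_index(ch)              # 0-based alphabet indices
  h <- (w - 1L) %/% 2L
  dash <- 23L
  # padded index vector: h dashes, sequence, h dashes
  padded <- c(rep.int(dash, h), idx0, rep.int(dash, h))
  # window p (1..w) of the example centred at residue i uses padded[i+p-1]
  rows <- rep(seq_len(L), each = w)
  pos <- rep(seq_len(w), times = L)
  cols <- (pos - 1L) * 24L + padded[rows + pos - 1L] + 1L
  Matrix::sparseMatrix(i = rows, j = cols, x = 1,
                       dims = c(L, 24L * w))
}

new_windowed_examples <- function(X, t, source_id, center, w) {
  structure(list(X = X, t = as.integer(t), source_id = source_id,
                 center = as.integer(center), w = w),
            class = "windowed_examples")
}

#' @export
print.windowed_examples <- function(x, ...) {
  cat("<windowed_examples> ", nrow(x$X), " examples, w = ", x$w,
      " (", sum(x$t), " positive)\n", sep = "")
  invisible(x)
}

#' Extract windowed one-of-n encoded examples from a sequence
#'
#' Places a sliding window of length `w` over every residue of the
#' sequence, one example per residue. Each window is encoded as a binary
#' vector of `24*w` components: one 24-component indicator block per window
#' position, with positions beyond either terminus encoded as the dummy
#' character `-`. The target is 1 iff the central residue is labelled `H`.
#'
#' @param seq An [annotated_sequence()].
#' @param cfg A [window_config()] or an odd integer window length.
#' @return A `"windowed_examples"` object: sparse matrix `X` (one row per
#'   residue), integer targets `t`, `source_id`, 0-based `center` indices,
#'   and the window length `w`.
#' @export
window_examples <- function(seq, cfg) {
  if (!inherits(cfg, "window_config")) cfg <- window_config(cfg)
  stopifnot(inherits(seq, "annot_seq"))
  X <- encode_windows(seq$residues, cfg$w)
  t <- as.integer(strsplit(seq$labels, "", fixed = TRUE)[[1]] == "H")
  new_windowed_examples(X, t, rep(seq$id, nrow(X)),
                        seq_len(nrow(X)) - 1L, cfg$w)
}

#' Windowed examples for a whole dataset
#'
#' @param seqs List of annotated sequences.
#' @param cfg Window configuration or odd integer length.
#' @return A single `"windowed_examples"` object concatenating all
#'   sequences' examples.
#' @export
window_dataset <- function(seqs, cfg) {
  if (!inherits(cfg, "window_config")) cfg <- window_config(cfg)
  if (length(seqs) == 0L) stop("empty dataset")
  parts <- lapply(seqs, window_examples, cfg = cfg)
  new_windowed_examples(
    X = do.call(rbind, lapply(parts, `[[`, "X")),
    t = unlist(lapply(parts, `[[`, "t")),
    source_id = unlist(lapply(parts, `[[`, "source_id")),
    center = unlist(lapply(parts, `[[`, "center")),
    w = cfg$w
  )
}

#' Rebalance a training set by discarding negative examples
#'
#' Hinge residues are heavily outnumbered by intradomain residues, so
#' training sets are rebalanced by randomly discarding negatively labelled
#' examples. All positives are kept; negatives are sampled uniformly
#' without replacement down to `neg_per_pos` negatives per positive
#' (flooring when inexact). Performed once per training set. The test-side
#' class balance is never altered.
#'
#' @param examples A `"windowed_examples"` object.
#' @param neg_per_pos Negatives retained per positive; the conventional
#'   1:9 positive-to-negative proportion corresponds to the default 9.
#' @param seed Integer seed making the subsample reproducible.
#' @return A `"windowed_examples"` object (also classed
#'   `"training_set"`) with an attribute `pos_neg_ratio` giving the ratio
#'   actually present.
#' @export
subsample_negatives <- function(examples, neg_per_pos = 9, seed = 1L) {
  stopifnot(inherits(examples, "windowed_examples"), neg_per_pos > 0)
  pos <- which(examples$t == 1L)
  neg <- which(examples$t == 0L)
  if (length(pos) == 0L) stop("training set has no positive examples")
  n_want <- floor(length(pos) * neg_per_pos)
  if (length(neg) < n_want) {
    warning("only ", length(neg), " negatives available for target ",
            n_want, "; keeping all")
    keep_neg <- neg
  } else if (length(neg) == n_want) {
    keep_neg <- neg
  } else {
    rs <- local_rng(seed)
    keep_neg <- sort(rs(function() neg[sample.int(length(neg), n_want)]))
  }
  keep <- sort(c(pos, keep_neg))
  out <- new_windowed_examples(examples$X[keep, , drop = FALSE],
                               examples$t[keep],
                               examples$source_id[keep],
                               examples$center[keep],
                               examples$w)
  class(out) <- c("training_set", class(out))
  attr(out, "pos_neg_ratio") <- length(keep_neg) / length(pos)
  out
}

# Run `f` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards. Returns a closure-runner.
local_rng <- function(seed) {
  function(f) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
    f()
  }
}

#' Dump window examples for audit
#'
#' Writes a TSV of `(source_id, center_1based, t)` rows.
#'
#' @param examples A `"windowed_examples"` object.
#' @param path Output path.
#' @export
write_window_audit <- function(examples, path) {
  utils::write.table(
    data.frame(source_id = examples$source_id,
               center_1based = examples$center + 1L,
               t = examples$t),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
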