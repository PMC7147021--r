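#' Per-amino-acid residue counts of an annotated dataset
#'
#' Tallies, for every residue type `a`, the number of occurrences in
#' hinge regions (`k`) and overall (`n`), together with the totals
#' `N_h` (residues in hinge regions) and `N` (all residues).
#'
#' @param seqs Non-empty list of [annotated_sequence()] objects.
#' @return An object of class `"hinge_counts"`: a data frame with columns
#'   `aa`, `k`, `n` and attributes `N_h` and `N`.
#' @export
count_residues <- function(seqs) {
  if (length(seqs) == 0L) stop("empty dataset")
  res <- strsplit(paste(vapply(seqs, `[[`, character(1), "residues"),
                        collapse = ""), "", fixed = TRUE)[[1]]
  lab <- strsplit(paste(vapply(seqs, `[[`, character(1), "labels"),
                        collapse = ""), "", fixed = TRUE)[[1]]
  f <- factor(res, levels = RESIDUE_ALPHABET)
  n <- as.integer(table(f))
  k <- as.integer(table(f[lab == "H"]))
  out <- data.frame(aa = RESIDUE_ALPHABET, k = k, n = n,
                    stringsAsFactors = FALSE)
  class(out) <- c("hinge_counts", "data.frame")
  attr(out, "N_h") <- sum(k)
  attr(out, "N") <- sum(n)
  out
}

#' Exact hypergeometric significance test for a residue count
#'
#' Tests whether `k` occurrences of an amino acid among the `N_h`
#' hinge-region residues are compatible with random assignment of that
#' amino acid (overall count `n` out of `N` residues) to hinge regions.
#' The reference distribution is Hypergeometric(N, n, N_h). The default
#' two-sided p-value uses the minimum-likelihood rule: the probabilities
#' of all outcomes whose point probability does not exceed that of `k`
#' are summed. One-sided alternatives are available.
#'
#' @param k Observed count of the amino acid in hinge regions.
#' @param N_h Total residues in hinge regions.
#' @param n Overall count of the amino acid.
#' @param N Total residues.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return The p-value, clipped to `[0, 1]`.
#' @export
hypergeometric_pvalue <- function(k, N_h, n, N,
                                  alternative = c("two.sided", "greater",
                                                  "less")) {
  alternative <- match.arg(alternative)
  if (N_h > N || n > N || k > min(n, N_h) || k < max(0, N_h + n - N) ||
      any(c(k, N_h, n, N) < 0)) {
    stop("inconsistent counts: need max(0, N_h + n - N) <= k <= min(n, N_h)",
         " and n, N_h <= N")
  }
  support <- max(0L, N_h + n - N):min(n, N_h)
  pmf <- stats::dhyper(support, m = n, n = N - n, k = N_h)
  p <- switch(alternative,
    two.sided = sum(pmf[pmf <= pmf[support == k] * (1 + 1e-7)]),
    greater = sum(pmf[support >= k]),
    less = sum(pmf[support <= k]))
  min(max(p, 0), 1)
}

#' Hinge Index propensity statistic with significance testing
#'
#' The Hinge Index of amino acid `a` is the log-likelihood ratio of its
#' frequency in hinge regions to its overall frequency,
#' `HI(a) = log( p(a|h) / p(a) )` with `p(a|h) = k_a / N_h` and
#' `p(a) = n_a / N` (natural logarithm). Positive values mark amino acids
#' favourable to hinge regions, negative values unfavourable ones, and
#' zero no preference. Significance is assessed per amino acid with the
#' exact hypergeometric test of [hypergeometric_pvalue()]; the null
#' hypothesis of random assignment is rejected at `p < alpha`.
#'
#' Amino acids absent from hinge regions (`k = 0` with `n > 0`) receive a
#' `-Inf` sentinel and are flagged `infinite`; no pseudo-count smoothing
#' is applied, and the p-value is still computed. Amino acids absent from
#' the dataset entirely (`n = 0`) get `NA`.
#'
#' @param counts A `"hinge_counts"` object from [count_residues()], or a
#'   list of annotated sequences (counted on the fly).
#' @param alpha Significance level; default 0.05.
#' @param alternative Sidedness passed to [hypergeometric_pvalue()].
#' @return An object of class `"hinge_index"`: a data frame with columns
#'   `aa`, `k`, `n`, `p_a`, `p_a_given_h`, `HI`, `infinite`, `p_value`,
#'   `significant`, sorted in alphabet order. Attributes `N_h`, `N`,
#'   `alpha` are carried along.
#' @export
hinge_index <- function(counts, alpha = 0.05,
                        alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (!inherits(counts, "hinge_counts")) counts <- count_residues(counts)
  N_h <- attr(counts, "N_h")
  N <- attr(counts, "N")
  if (N_h == 0L) stop("no hinge residues in dataset (N_h = 0)")
  p_a <- counts$n / N
  p_ah <- counts$k / N_h
  HI <- ifelse(counts$n == 0L, NA_real_,
               ifelse(counts$k == 0L, -Inf, log(p_ah / p_a)))
  p_value <- vapply(seq_len(nrow(counts)), function(i) {
    if (counts$n[i] == 0L) return(NA_real_)
    hypergeometric_pvalue(counts$k[i], N_h, counts$n[i], N,
                          alternative = alternative)
  }, numeric(1))
  out <- data.frame(aa = counts$aa, k = counts$k, n = counts$n,
                    p_a = p_a, p_a_given_h = p_ah, HI = HI,
                    infinite = is.infinite(HI),
                    p_value = p_value,
                    significant = !is.na(p_value) & p_value < alpha,
                    stringsAsFactors = FALSE)
  class(out) <- c("hinge_index", "data.frame")
  attr(out, "N_h") <- N_h
  attr(out, "N") <- N
  attr(out, "alpha") <- alpha
  out
}

#' Write a Hinge Index report
#'
#' TSV with columns `amino_acid`, `k`, `n`, `HI`, `p_value`,
#' `significant`, sorted by `HI` ascending (`-Inf` sentinels first,
#' `NA` rows last).
#'
#' @param hi A `"hinge_index"` object.
#' @param path Output path.
#' @export
write_hinge_index <- function(hi, path) {
  ord <- order(hi$HI, na.last = TRUE)
  df <- data.frame(amino_acid = hi$aa, k = hi$k, n = hi$n, HI = hi$HI,
                   p_value = hi$p_value, significant = hi$significant)
  utils::write.table(df[ord, ], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Plot Hinge Index values with p-values
#'
#' Bar plot of per-amino-acid p-values with the HI values overlaid as a
#' line, amino acids sorted by HI ascending. `-Inf` sentinels are drawn
#' at the bottom axis limit and marked.
#'
#' @param hi A `"hinge_index"` object.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot_hinge_index <- function(hi, ...) {
  alpha <- attr(hi, "alpha")
  if (is.null(alpha)) alpha <- 0.05
  keep <- !is.na(hi$HI)
  hi <- hi[keep, ]
  ord <- order(hi$HI)
  hi <- hi[ord, ]
  finite <- is.finite(hi$HI)
  lo <- if (any(finite)) min(hi$HI[finite]) else -1
  hi_plot <- ifelse(finite, hi$HI, lo - 0.5)
  mid <- graphics::barplot(hi$p_value, names.arg = hi$aa,
                           col = "burlywood", border = NA,
                           ylab = "p-value", ...)
  graphics::abline(h = alpha, lty = 3)
  graphics::par(new = TRUE)
  graphics::plot(mid, hi_plot, type = "b", col = "blue", pch = 16,
                 axes = FALSE, xlab = "", ylab = "")
  graphics::axis(4, col.axis = "blue")
  graphics::mtext("HI", side = 4, line = 2, col = "blue")
  graphics::abline(h = 0, lty = 2)
  invisible(hi)
}
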