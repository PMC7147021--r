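check_scored_labels <- function(scores, labels, need_both = TRUE) {
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length")
  }
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  if (need_both && (sum(labels == 1) == 0L || sum(labels == 0) == 0L)) {
    stop("both classes must be present")
  }
  invisible(NULL)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic: the proportion of
#' (positive, negative) pairs in which the positive scores higher, with
#' ties counted half. This equals the trapezoidal area under the
#' tie-grouped ROC curve, and makes a constant scorer exactly 0.5.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 labels (1 = hinge).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  check_scored_labels(scores, labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve
#'
#' Threshold-swept ROC curve with tied scores grouped into single steps.
#' Points run from (0, 0) to (1, 1), monotone in both coordinates; the
#' trapezoidal area equals [auroc()].
#'
#' @inheritParams auroc
#' @return An object of class `"curve_result"` with a `points` data frame
#'   (`x` = false positive rate, `y` = true positive rate), `area` and
#'   `kind = "roc"`.
#' @export
roc_curve <- function(scores, labels) {
  check_scored_labels(scores, labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  # group tied scores into one threshold step
  steps <- which(!duplicated(s))          # first index of each distinct score
  ends <- c(steps[-1L] - 1L, length(s))
  tp <- cumsum(l)[ends]
  fp <- ends - tp
  n1 <- sum(l)
  n0 <- length(l) - n1
  pts <- data.frame(x = c(0, fp / n0, 1), y = c(0, tp / n1, 1))
  pts <- unique(pts)
  area <- sum(diff(pts$x) * (utils::head(pts$y, -1) +
                               utils::tail(pts$y, -1)) / 2)
  structure(list(points = pts, area = area, kind = "roc"),
            class = "curve_result")
}

#' Area under the precision-recall curve
#'
#' Step-wise (non-interpolated) area: thresholds sweep the distinct
#' scores in decreasing order and each recall increment contributes the
#' precision at that threshold, `sum_k (R_k - R_{k-1}) P_k`. Dependent on
#' class prevalence; a random scorer approaches the positive-class
#' proportion.
#'
#' @inheritParams auroc
#' @return AUPRC in `(0, 1]`.
#' @export
auprc <- function(scores, labels) {
  pr_curve(scores, labels)$area
}

#' Precision-recall curve
#'
#' @inheritParams auroc
#' @return A `"curve_result"` with `points` (`x` = recall,
#'   `y` = precision), step-wise `area`, and `kind = "pr"`.
#' @export
pr_curve <- function(scores, labels) {
  check_scored_labels(scores, labels, need_both = FALSE)
  if (sum(labels == 1) == 0L) stop("at least one positive is required")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  steps <- which(!duplicated(s))
  ends <- c(steps[-1L] - 1L, length(s))
  tp <- cumsum(l)[ends]
  n1 <- sum(l)
  recall <- tp / n1
  precision <- tp / ends
  area <- sum(diff(c(0, recall)) * precision)
  structure(list(points = data.frame(x = recall, y = precision),
                 area = area, kind = "pr"),
            class = "curve_result")
}

#' @export
print.curve_result <- function(x, ...) {
  cat("<curve_result> ", toupper(x$kind), ", area = ",
      format(x$area, digits = 4), " (", nrow(x$points), " points)\n",
      sep = "")
  invisible(x)
}

#' DeLong's test for two paired AUROCs
#'
#' Tests the null hypothesis that the difference between two empirical
#' AUROCs, computed from two classifiers scored on the same test set, is
#' explained by estimator variance. The variance of the difference is
#' estimated from the structural components
#' `V10_i = mean_j psi(s_i+, s_j-)` and `V01_j = mean_i psi(s_i+, s_j-)`
#' (with `psi` = 1, 1/2, 0 for greater/tied/smaller), and the two-sided
#' p-value from the normal approximation. Identical score vectors give a
#' difference of 0 and p = 1.
#'
#' @param scores1,scores2 Score vectors of the two classifiers.
#' @param labels Common 0/1 label vector (the comparison must be paired).
#' @param labels2 Optional second label vector; if supplied it must be
#'   identical to `labels`, otherwise an error is raised.
#' @return List with `auroc1`, `auroc2`, `var_diff`, `z` and `p_value`.
#' @export
delong_test <- function(scores1, scores2, labels, labels2 = NULL) {
  if (!is.null(labels2) && !identical(as.numeric(labels),
                                      as.numeric(labels2))) {
    stop("unpaired comparison unsupported: label vectors differ")
  }
  check_scored_labels(scores1, labels)
  check_scored_labels(scores2, labels)
  pos <- labels == 1
  structural <- function(s) {
    sp <- s[pos]
    sn <- s[!pos]
    psi <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
    list(v10 = rowMeans(psi), v01 = colMeans(psi),
         auc = mean(psi))
  }
  c1 <- structural(scores1)
  c2 <- structural(scores2)
  m <- sum(pos)
  n <- sum(!pos)
  s10 <- stats::cov(cbind(c1$v10, c2$v10))
  s01 <- stats::cov(cbind(c1$v01, c2$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- c1$auc - c2$auc
  if (var_diff <= 0 || !is.finite(var_diff)) {
    p <- if (abs(d) < .Machine$double.eps^0.5) 1 else 0
    z <- if (p == 1) 0 else sign(d) * Inf
  } else {
    z <- d / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auroc1 = c1$auc, auroc2 = c2$auc, var_diff = var_diff, z = z,
       p_value = p)
}

#' Split sequences into train and test sets
#'
#' Splitting is performed at sequence level, never at window level, so
#' that overlapping near-duplicate windows of one sequence cannot leak
#' between the parts.
#'
#' @param seqs List of annotated sequences (length at least 2).
#' @param test_fraction Proportion assigned to the test set, in (0, 1).
#' @param seed Integer seed; identical seeds give identical splits.
#' @return List with elements `train` and `test`, a disjoint partition of
#'   the input.
#' @export
split_train_test <- function(seqs, test_fraction, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  if (length(seqs) < 2L) stop("need at least 2 sequences to split")
  n_test <- max(1L, round(length(seqs) * test_fraction))
  if (n_test >= length(seqs)) n_test <- length(seqs) - 1L
  run <- local_rng(seed)
  idx <- run(function() sample(seq_along(seqs), n_test))
  list(train = seqs[-idx], test = seqs[sort(idx)])
}

#' Assign sequences to cross-validation folds
#'
#' Fold sizes differ by at most one. Sequences containing hinge residues
#' are distributed round-robin first so that, where possible, every fold
#' holds at least one hinge-bearing sequence.
#'
#' @param seqs List of annotated sequences.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return An object of class `"fold_plan"`: integer fold index per
#'   sequence (named by sequence id), with `k` and `seed` attributes.
#' @export
make_folds <- function(seqs, k, seed = 1L) {
  stopifnot(k >= 2, k <= length(seqs))
  has_h <- vapply(seqs, function(s) grepl("H", s$labels, fixed = TRUE),
                  logical(1))
  run <- local_rng(seed)
  resample <- function(x) x[sample.int(length(x))]
  ord <- run(function() c(resample(which(has_h)), resample(which(!has_h))))
  assignment <- integer(length(seqs))
  assignment[ord] <- rep_len(seq_len(k), length(seqs))
  names(assignment) <- vapply(seqs, `[[`, character(1), "id")
  structure(assignment, k = k, seed = seed, class = "fold_plan")
}

#' Nested cross-validation at sequence level
#'
#' For each of `k` outer folds the pipeline is run with all remaining
#' sequences as training material and the fold as test material; any
#' hyper-parameter tuning belongs inside the pipeline, so each fold's
#' AUROC is computed on sequences never used for training or tuning of
#' that fold's model. Folds whose test windows lack positive examples are
#' flagged and excluded from the mean, with a warning.
#'
#' @param seqs List of annotated sequences.
#' @param k Number of outer folds.
#' @param pipeline Function `(train_seqs, test_seqs)` returning a list
#'   with numeric `scores` and 0/1 `labels` for the test residues (see
#'   [klr_pipeline()]).
#' @param seed Integer seed for the fold assignment.
#' @return Data frame with one row per fold: `fold`, `auroc`, `n_pos`,
#'   `n`, `flagged`; the mean AUROC over unflagged folds is attached as
#'   attribute `"mean_auroc"`.
#' @export
nested_cv <- function(seqs, k, pipeline, seed = 1L) {
  plan <- make_folds(seqs, k, seed)
  rows <- lapply(seq_len(k), function(f) {
    test <- seqs[plan == f]
    train <- seqs[plan != f]
    out <- pipeline(train, test)
    n_pos <- sum(out$labels == 1)
    flagged <- n_pos == 0L || all(out$labels == 1)
    data.frame(fold = f,
               auroc = if (flagged) NA_real_ else
                 auroc(out$scores, out$labels),
               n_pos = n_pos, n = length(out$labels), flagged = flagged)
  })
  res <- do.call(rbind, rows)
  if (any(res$flagged)) {
    warning(sum(res$flagged), " fold(s) lacked positive test examples ",
            "and were excluded from the mean")
  }
  attr(res, "mean_auroc") <- mean(res$auroc[!res$flagged])
  res
}

#' Paired t-test across cross-validation folds
#'
#' Standard two-sided paired t-test on the per-fold differences. If every
#' difference is exactly zero the p-value is defined as 1; a zero-variance
#' but non-zero difference is a degenerate case and raises an error.
#'
#' @param a,b Numeric vectors of per-fold values, paired by fold.
#' @return Two-sided p-value.
#' @export
paired_ttest <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  if (stats::sd(d) == 0) {
    if (all(d == 0)) return(1)
    stop("degenerate paired t-test: constant non-zero differences")
  }
  stats::t.test(a, b, paired = TRUE)$p.value
}

#' A standard KLR training-and-scoring pipeline
#'
#' Factory returning a pipeline function suitable for [nested_cv()],
#' [imbalance_sweep()] and [sweep_windows()]: window both sequence sets,
#' rebalance the training windows by [subsample_negatives()], optionally
#' tune hyper-parameters on the training set, train, and score every test
#' residue. The test set is never subsampled.
#'
#' @param w Window length.
#' @param spec A [kernel_spec()] (ignored for the tuned family if
#'   `tune = TRUE`).
#' @param cfg A [training_config()].
#' @param neg_per_pos Training negatives per positive; default 9.
#' @param tune If `TRUE`, run [tune_hyperparams()] on the training
#'   windows before fitting.
#' @param seed Seed for the negative subsample.
#' @return Function `(train_seqs, test_seqs, neg_per_pos = ...)` returning
#'   `list(scores, labels)`.
#' @export
klr_pipeline <- function(w, spec = kernel_spec("linear"),
                         cfg = training_config(), neg_per_pos = 9,
                         tune = FALSE, seed = 1L) {
  force(list(w, spec, cfg, neg_per_pos, tune, seed))
  function(train_seqs, test_seqs, neg_per_pos_override = NULL) {
    npp <- if (is.null(neg_per_pos_override)) neg_per_pos else
      neg_per_pos_override
    train_w <- window_dataset(train_seqs, w)
    train_s <- subsample_negatives(train_w, npp, seed = seed)
    use_spec <- spec
    use_cfg <- cfg
    if (tune) {
      tuned <- tune_hyperparams(train_s, spec$family,
                                init = list(gamma = cfg$gamma,
                                            c = spec$c,
                                            theta = spec$theta),
                                d = spec$d)
      use_spec <- tuned$spec
      use_cfg <- tuned$cfg
    }
    model <- train_klr(train_s, use_spec, use_cfg)
    test_w <- window_dataset(test_seqs, w)
    stopifnot(length(test_w$t) == sum(vapply(test_seqs, function(s)
      nchar(s$residues), integer(1))))  # test side never subsampled
    list(scores = predict(model, test_w), labels = test_w$t)
  }
}

#' AUROC across training-set class-imbalance ratios
#'
#' Retrains the pipeline at each positive-to-negative training ratio and
#' evaluates on one fixed, never-subsampled test set.
#'
#' @param train_seqs,test_seqs Annotated sequence lists.
#' @param ratios Numeric vector of negatives-per-positive values.
#' @param pipeline A pipeline function from [klr_pipeline()].
#' @return Data frame `(neg_per_pos, auroc)` with one row per ratio.
#' @export
imbalance_sweep <- function(train_seqs, test_seqs, ratios, pipeline) {
  rows <- lapply(ratios, function(r) {
    out <- pipeline(train_seqs, test_seqs, neg_per_pos_override = r)
    data.frame(neg_per_pos = r, auroc = auroc(out$scores, out$labels))
  })
  if (length(rows) == 0L) {
    return(data.frame(neg_per_pos = numeric(0), auroc = numeric(0)))
  }
  do.call(rbind, rows)
}

#' AUROC/AUPRC sweep over window lengths and kernels
#'
#' Trains one model per (window length, kernel) combination on the
#' training sequences and evaluates AUROC and AUPRC on the fixed test
#' sequences.
#'
#' @param train_seqs,test_seqs Annotated sequence lists.
#' @param windows Integer vector of odd window lengths.
#' @param kernels Named list of [kernel_spec()] objects.
#' @param cfg A [training_config()].
#' @param neg_per_pos Training negatives per positive.
#' @param tune Tune hyper-parameters per combination.
#' @param seed Seed for negative subsampling.
#' @return Data frame `(window_length, kernel, auroc, auprc)`.
#' @export
sweep_windows <- function(train_seqs, test_seqs, windows,
                          kernels = list(linear = kernel_spec("linear")),
                          cfg = training_config(), neg_per_pos = 9,
                          tune = FALSE, seed = 1L) {
  rows <- list()
  for (w in windows) {
    for (kname in names(kernels)) {
      pipe <- klr_pipeline(w, kernels[[kname]], cfg, neg_per_pos,
                           tune = tune, seed = seed)
      out <- pipe(train_seqs, test_seqs)
      rows[[length(rows) + 1L]] <-
        data.frame(window_length = w, kernel = kname,
                   auroc = auroc(out$scores, out$labels),
                   auprc = auprc(out$scores, out$labels))
    }
  }
  do.call(rbind, rows)
}

#' Write curve points or sweep tables as TSV
#'
#' @param x A `"curve_result"` or data frame.
#' @param path Output path.
#' @export
write_eval_tsv <- function(x, path) {
  df <- if (inherits(x, "curve_result")) x$points else x
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
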