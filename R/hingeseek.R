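#' Global-alignment percent identity of two sequences
#'
#' Needleman-Wunsch global alignment under a simple scoring scheme
#' (match +1, mismatch 0, linear gap -1, used only to choose the
#' alignment path); identity is the number of matched columns divided by
#' the total number of alignment columns, times 100. Symmetric in its
#' arguments. This is the default identity function for redundancy
#' filtering and ensemble selection; any function with the same signature
#' can be substituted.
#'
#' @param a,b Non-empty residue strings (or `annot_seq` objects).
#' @return Percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(a, b) {
  if (inherits(a, "annot_seq")) a <- a$residues
  if (inherits(b, "annot_seq")) b <- b$residues
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty sequence")
  letters_all <- unique(c(strsplit(a, "")[[1]], strsplit(b, "")[[1]]))
  sub <- matrix(0, length(letters_all), length(letters_all),
                dimnames = list(letters_all, letters_all))
  diag(sub) <- 1
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::BString(a), Biostrings::BString(b),
    substitutionMatrix = sub, gapOpening = 0, gapExtension = 1,
    type = "global")
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  100 * sum(pa == pb & pa != "-") / length(pa)
}

#' Train a bootstrap ensemble of quadratic KLR models
#'
#' Each ensemble member is trained on a bootstrap resample of the
#' training sequences (sampled with replacement at sequence level, same
#' number of sequences as the input), which is then windowed, rebalanced
#' to 1:9 positives to negatives, optionally tuned, and fitted. Member
#' training-sequence identities are recorded so that predictions can be
#' restricted to members never exposed to sequences similar to a query.
#' Members are held in dual form; primal weights are materialised during
#' aggregation.
#'
#' @param seqs Non-empty list of annotated training sequences.
#' @param n_models Number of bootstrap members (at least 1).
#' @param w Window length; default 87, the optimum for quadratic models
#'   on strictly filtered data.
#' @param seed Integer master seed; member seeds are derived from it, so
#'   the whole ensemble is reproducible.
#' @param spec Kernel for the members; default quadratic with `c = 1`.
#' @param cfg A [training_config()].
#' @param neg_per_pos Training negatives per positive; default 9.
#' @param tune Tune `gamma` and `c` per member by approximate LOO.
#' @return An object of class `"hinge_ensemble"`: list of members (each
#'   `model`, `train_ids`, `seed`), window length `w`, and the kernel
#'   family.
#' @export
train_ensemble <- function(seqs, n_models, w = 87L, seed = 1L,
                           spec = kernel_spec("polynomial", d = 2L, c = 1),
                           cfg = training_config(), neg_per_pos = 9,
                           tune = FALSE) {
  if (length(seqs) == 0L) stop("empty training set")
  stopifnot(n_models >= 1)
  members <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    mseed <- substream_seed(seed, m)
    run <- local_rng(mseed)
    idx <- run(function() sample.int(length(seqs), length(seqs),
                                     replace = TRUE))
    boot <- seqs[idx]
    train_w <- window_dataset(boot, w)
    train_s <- subsample_negatives(train_w, neg_per_pos, seed = mseed)
    use_spec <- spec
    use_cfg <- cfg
    if (tune) {
      tuned <- tune_hyperparams(train_s, spec$family,
                                init = list(gamma = cfg$gamma, c = spec$c,
                                            theta = spec$theta),
                                d = spec$d)
      use_spec <- tuned$spec
      use_cfg <- tuned$cfg
    }
    model <- train_klr(train_s, use_spec, use_cfg)
    members[[m]] <- list(model = model,
                         train_ids = vapply(boot, `[[`, character(1), "id"),
                         seed = mseed)
  }
  structure(list(members = members, w = as.integer(w),
                 family = spec$family, n_members = n_models),
            class = "hinge_ensemble")
}

#' @export
print.hinge_ensemble <- function(x, ...) {
  cat("<hinge_ensemble> ", x$n_members, " ", x$family,
      " members, window ", x$w, "\n", sep = "")
  invisible(x)
}

#' Select ensemble members distant from a query sequence
#'
#' Keeps only the members none of whose training sequences exceeds the
#' identity threshold with the query, so the aggregated prediction is an
#' unbiased benchmark for sequences related to the training data. The
#' selection is monotone in the threshold.
#'
#' @param ens A `"hinge_ensemble"`.
#' @param query Residue string (or `annot_seq`).
#' @param identity_threshold Percent identity in `(0, 100]`; members with
#'   any training-sequence identity strictly above it are dropped.
#' @param train_seqs Named list or list of `annot_seq` giving the
#'   sequences behind the recorded training ids.
#' @param identity_fn Identity function; default [pairwise_identity()].
#' @return The sub-ensemble (same class) with attribute `"identities"`
#'   giving the per-training-sequence identities computed.
#' @export
select_models <- function(ens, query, identity_threshold, train_seqs,
                          identity_fn = pairwise_identity) {
  stopifnot(inherits(ens, "hinge_ensemble"),
            identity_threshold > 0, identity_threshold <= 100)
  if (inherits(query, "annot_seq")) query <- query$residues
  ids <- vapply(train_seqs, `[[`, character(1), "id")
  idents <- vapply(train_seqs, function(s)
    identity_fn(query, s$residues), numeric(1))
  names(idents) <- ids
  keep <- vapply(ens$members, function(m) {
    known <- m$train_ids[m$train_ids %in% ids]
    all(idents[known] <= identity_threshold)
  }, logical(1))
  if (!any(keep)) {
    stop("no ensemble members survive the ", identity_threshold,
         "% identity filter; raise the threshold")
  }
  out <- ens
  out$members <- ens$members[keep]
  out$n_members <- sum(keep)
  attr(out, "identities") <- idents
  out
}

#' Aggregate ensemble members into a single primal model
#'
#' Extracts each selected member's primal weights and averages them
#' component-wise (including the bias), producing one directly evaluable
#' model. Averaging is performed incrementally in the unified quadratic
#' form, so members tuned to different kernel offsets average cleanly.
#'
#' @param ens A `"hinge_ensemble"` (typically after [select_models()]).
#' @return A `"primal_model"`.
#' @export
aggregate_ensemble <- function(ens) {
  stopifnot(inherits(ens, "hinge_ensemble"), length(ens$members) >= 1)
  pms <- NULL
  k <- length(ens$members)
  for (m in ens$members) {
    pm <- primal_model(m$model)
    if (is.null(pms)) {
      if (!is.null(pm$Q)) pm$Q <- pm$Q / k
      pm$lin <- pm$lin / k
      pm$b0 <- pm$b0 / k
      pms <- pm
    } else {
      if (pm$dim != pms$dim || pm$family != pms$family) {
        stop("dimension mismatch across ensemble members")
      }
      if (!is.null(pm$Q)) pms$Q <- pms$Q + pm$Q / k
      pms$lin <- pms$lin + pm$lin / k
      pms$b0 <- pms$b0 + pm$b0 / k
    }
  }
  # per-member provenance fields are meaningless after averaging
  pms$c <- NA_real_
  pms$q <- NULL
  pms$sum_alpha <- NA_real_
  pms
}

#' Per-residue hinge prediction for a query sequence
#'
#' Windows the query, evaluates the model on every residue-centred
#' window, and calls each residue hinge iff its probability is strictly
#' above the threshold. The reported confidence is the predicted
#' probability itself.
#'
#' @param model A `"primal_model"` (single model or ensemble aggregate).
#' @param seq Residue string over the 23-letter alphabet, or `annot_seq`.
#' @param w Window length (must match the model); default taken from the
#'   model when recorded.
#' @param threshold Call threshold in `(0, 1)`.
#' @param id Sequence identifier for the report.
#' @return An object of class `"hinge_prediction"`: data frame with
#'   columns `sequence_id`, `position` (1-based), `residue`,
#'   `probability`, `call`; attributes `threshold` and `n_models_used`.
#' @export
predict_sequence <- function(model, seq, w = NULL, threshold = 0.5,
                             id = "query") {
  if (inherits(seq, "annot_seq")) {
    id <- seq$id
    seq <- seq$residues
  }
  if (is.null(w)) {
    w <- model$dim %/% 24L
  }
  if (24L * w != model$dim) {
    stop("window length ", w, " does not match model dimension")
  }
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!ch %in% RESIDUE_ALPHABET)
  if (length(bad) > 0L) {
    stop("illegal residue character '", ch[bad[1L]], "' at position ",
         bad[1L])
  }
  X <- encode_windows(seq, w)
  p <- predict(model, X)
  out <- data.frame(sequence_id = id, position = seq_along(ch),
                    residue = ch, probability = p,
                    call = classify(p, threshold),
                    stringsAsFactors = FALSE)
  structure(out, class = c("hinge_prediction", "data.frame"),
            threshold = threshold, n_models_used = 1L)
}

#' End-to-end ensemble prediction with identity filtering
#'
#' Convenience wrapper: select members below the identity threshold,
#' aggregate their weights, and predict every residue of the query.
#'
#' @param ens A `"hinge_ensemble"`.
#' @param train_seqs Training sequences behind the ensemble.
#' @param query Residue string or `annot_seq`.
#' @param identity_max Identity threshold in percent; default 90.
#' @param threshold Call threshold; default 0.5.
#' @param id Query identifier.
#' @return A `"hinge_prediction"` (see [predict_sequence()]) whose
#'   `n_models_used` attribute records the surviving member count.
#' @export
hingeseek_predict <- function(ens, train_seqs, query, identity_max = 90,
                              threshold = 0.5, id = "query") {
  sub <- select_models(ens, query, identity_max, train_seqs)
  agg <- aggregate_ensemble(sub)
  out <- predict_sequence(agg, query, w = ens$w, threshold = threshold,
                          id = id)
  attr(out, "n_models_used") <- sub$n_members
  out
}

#' Write a per-residue prediction report
#'
#' TSV with columns `sequence_id`, `position_1based`, `residue`,
#' `probability`, `call`, preceded by comment lines logging the threshold
#' and number of models used.
#'
#' @param pred A `"hinge_prediction"`.
#' @param path Output path.
#' @export
write_prediction <- function(pred, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# threshold\t", attr(pred, "threshold")),
    paste0("# n_models_used\t", attr(pred, "n_models_used"))), con)
  df <- data.frame(sequence_id = pred$sequence_id,
                   position_1based = pred$position,
                   residue = pred$residue,
                   probability = sprintf("%.6f", pred$probability),
                   call = pred$call)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
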