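# drop generator bookkeeping attributes so lists compare as plain records
unclass_attrs <- function(seqs) {
  attr(seqs, "tallies") <- NULL
  seqs
}

# canonical planted composition signal used across discrimination tests:
# hinge regions enriched in Pro/Ser/Gly, devoid of Cys, depleted in large
# hydrophobics (mirrors the qualitative propensity pattern of real hinges)
demo_signal <- function() {
  list(P = 6, S = 3, G = 2, C = 0, W = 0.4, F = 0.4, I = 0.4, L = 0.5,
       V = 0.5)
}

demo_hinge_probs <- function() {
  boost_aa_probs(default_aa_probs(), demo_signal())
}

# small deterministic training set for KLR unit tests
small_training_set <- function(n_seq = 6, w = 5, seed = 3, npp = 5) {
  cfg <- generator_config(n_sequences = n_seq, seed = seed,
                          domain_length_range = c(10L, 25L),
                          hinge_length_range = c(2L, 4L),
                          hinge_aa_probs = demo_hinge_probs())
  ds <- generate_dataset(cfg)
  subsample_negatives(window_dataset(ds, w), npp, seed = seed)
}

# random one-of-n window matrix (dense) for kernel identity checks
random_windows <- function(n, w, seed = 1) {
  set.seed(seed)
  X <- matrix(0, n, 24 * w)
  for (i in seq_len(n)) {
    picks <- sample.int(24L, w, replace = TRUE)
    X[i, (seq_len(w) - 1L) * 24L + picks] <- 1
  }
  X
}
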