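# Independent brute-force oracles used to pin expected values.

# exhaustive hypergeometric two-sided p-value (minimum-likelihood rule),
# pmf from choose() directly
oracle_hyper_p <- function(k, N_h, n, N) {
  support <- max(0, N_h + n - N):min(n, N_h)
  pmf <- choose(n, support) * choose(N - n, N_h - support) / choose(N, N_h)
  sum(pmf[pmf <= pmf[support == k] * (1 + 1e-7)])
}

# AUROC by exhaustive pair counting with half credit for ties
oracle_auroc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# DeLong variance of the AUROC difference via explicit double loops
oracle_delong <- function(s1, s2, labels) {
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  m <- length(pos); n <- length(neg)
  psi <- function(a, b) if (a > b) 1 else if (a == b) 0.5 else 0
  comp <- function(s) {
    v10 <- numeric(m); v01 <- numeric(n)
    for (i in seq_len(m)) {
      for (j in seq_len(n)) {
        p <- psi(s[pos[i]], s[neg[j]])
        v10[i] <- v10[i] + p / n
        v01[j] <- v01[j] + p / m
      }
    }
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  c1 <- comp(s1); c2 <- comp(s2)
  var_diff <- (stats::var(c1$v10) + stats::var(c2$v10) -
                 2 * stats::cov(c1$v10, c2$v10)) / m +
    (stats::var(c1$v01) + stats::var(c2$v01) -
       2 * stats::cov(c1$v01, c2$v01)) / n
  list(auc1 = c1$auc, auc2 = c2$auc, var_diff = var_diff)
}

# brute-force leave-one-out cross-entropy: retrain without each example
oracle_brute_loo <- function(train, spec, cfg) {
  ell <- nrow(train$X)
  ce <- numeric(ell)
  for (i in seq_len(ell)) {
    sub <- list(X = train$X[-i, , drop = FALSE], t = train$t[-i])
    m <- suppressWarnings(train_klr(sub, spec, cfg))
    y <- predict(m, train$X[i, , drop = FALSE])
    y <- min(max(y, 1e-12), 1 - 1e-12)
    ce[i] <- -(train$t[i] * log(y) + (1 - train$t[i]) * log(1 - y))
  }
  mean(ce)
}

# global-alignment identity oracle for tiny cases: exact NW dynamic
# programme (match +1, mismatch 0, gap -1), identity = matches / columns
oracle_nw_identity <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- -(0:n); S[1, ] <- -(0:m)
  for (i in 1:n) for (j in 1:m) {
    S[i + 1, j + 1] <- max(S[i, j] + (A[i] == B[j]),
                           S[i, j + 1] - 1, S[i + 1, j] - 1)
  }
  # traceback counting matches and columns
  i <- n; j <- m; matches <- 0; cols <- 0
  while (i > 0 || j > 0) {
    cols <- cols + 1
    if (i > 0 && j > 0 && S[i + 1, j + 1] == S[i, j] + (A[i] == B[j])) {
      matches <- matches + (A[i] == B[j]); i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] - 1) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  100 * matches / cols
}
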