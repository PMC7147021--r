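test_that("AUROC equals exhaustive pair counting", {
  expect_equal(auroc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(c(0.1, 0.2, 0.3, 0.4), c(0, 1, 0, 1)), 0.75)

  set.seed(71)
  for (rep in 1:20) {
    n <- sample(5:200, 1)
    scores <- round(runif(n), 2)  # force ties
    labels <- rbinom(n, 1, 0.3)
    if (length(unique(labels)) < 2) next
    expect_equal(auroc(scores, labels), oracle_auroc(scores, labels),
                 tolerance = 1e-12)
  }
  expect_error(auroc(c(1, 2), c(1, 1)), "both classes")
})

test_that("AUROC matches pROC as an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  scores <- runif(300)
  labels <- rbinom(300, 1, 0.2)
  expect_equal(auroc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              quiet = TRUE))),
               tolerance = 1e-10)
})

test_that("AUROC symmetry and monotone-invariance properties hold", {
  set.seed(9)
  for (rep in 1:10) {
    scores <- sample(seq(0, 1, by = 0.05), 60, replace = TRUE)
    labels <- rbinom(60, 1, 0.4)
    if (length(unique(labels)) < 2) next
    a <- auroc(scores, labels)
    expect_equal(a + auroc(-scores, labels), 1, tolerance = 1e-12)
    expect_equal(auroc(plogis(5 * scores - 2), labels), a,
                 tolerance = 1e-12)
  }
  expect_equal(auroc(rep(0.4, 10), rbinom(10, 1, 0.5) |>
                       (\(l) { l[1] <- 1; l[2] <- 0; l })()), 0.5)
})

test_that("ROC curves run from (0,0) to (1,1) monotonically", {
  set.seed(21)
  scores <- round(runif(100), 1)
  labels <- rbinom(100, 1, 0.3)
  rc <- roc_curve(scores, labels)
  expect_equal(rc$points$x[1], 0)
  expect_equal(rc$points$y[1], 0)
  expect_equal(rc$points$x[nrow(rc$points)], 1)
  expect_equal(rc$points$y[nrow(rc$points)], 1)
  expect_true(all(diff(rc$points$x) >= 0))
  expect_true(all(diff(rc$points$y) >= 0))
  expect_equal(rc$area, auroc(scores, labels), tolerance = 1e-12)
})

test_that("AUPRC behaves at its boundary cases", {
  expect_equal(auprc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  # single positive ranked first
  expect_equal(auprc(c(0.99, 0.5, 0.4, 0.3), c(1, 0, 0, 0)), 1.0)
  expect_error(auprc(c(0.5, 0.4), c(0, 0)), "positive")
})

test_that("random-scorer AUPRC approaches prevalence", {
  set.seed(17)
  n <- 20000
  labels <- rbinom(n, 1, 0.0294)
  scores <- runif(n)
  expect_equal(auprc(scores, labels), mean(labels), tolerance = 0.2)
})

test_that("DeLong components match the brute-force double loop", {
  set.seed(3)
  labels <- c(rep(1, 12), rep(0, 28))
  s1 <- round(runif(40), 2)
  s2 <- round(plogis(2 * s1 - 1 + rnorm(40, 0, 0.3)), 2)
  got <- delong_test(s1, s2, labels)
  want <- oracle_delong(s1, s2, labels)
  expect_equal(got$auroc1, want$auc1, tolerance = 1e-12)
  expect_equal(got$auroc2, want$auc2, tolerance = 1e-12)
  expect_equal(got$var_diff, want$var_diff, tolerance = 1e-12)
})

test_that("DeLong test edge behaviour and symmetry", {
  set.seed(8)
  labels <- rbinom(40, 1, 0.4)
  labels[1:2] <- c(1, 0)
  s <- runif(40)
  same <- delong_test(s, s, labels)
  expect_equal(same$p_value, 1)
  expect_equal(same$auroc1 - same$auroc2, 0)

  s2 <- runif(40)
  ab <- delong_test(s, s2, labels)
  ba <- delong_test(s2, s, labels)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)

  expect_error(delong_test(s, s2, labels, labels2 = 1 - labels),
               "unpaired")

  # perfect vs random on a large sample is significant
  set.seed(12)
  lab <- rbinom(2000, 1, 0.1)
  perfect <- lab + runif(2000, 0, 0.5)
  random <- runif(2000)
  expect_lt(delong_test(perfect, random, lab)$p_value, 0.05)
})

test_that("train/test splitting partitions at sequence level", {
  ds <- generate_dataset(generator_config(n_sequences = 10, seed = 3))
  sp <- split_train_test(ds, 0.1, seed = 5)
  expect_length(sp$test, 1L)
  expect_length(sp$train, 9L)
  ids <- function(x) vapply(x, `[[`, character(1), "id")
  expect_length(intersect(ids(sp$train), ids(sp$test)), 0L)
  expect_setequal(c(ids(sp$train), ids(sp$test)), ids(ds))
  sp2 <- split_train_test(ds, 0.1, seed = 5)
  expect_identical(ids(sp2$test), ids(sp$test))
  expect_error(split_train_test(ds[1], 0.1), "at least 2")
})

test_that("fold plans are balanced and hinge-stratified", {
  ds <- generate_dataset(generator_config(n_sequences = 20, seed = 3))
  plan <- make_folds(ds, 10, seed = 2)
  expect_equal(sort(as.integer(table(plan))), rep(2L, 10))
  expect_setequal(names(plan), vapply(ds, `[[`, character(1), "id"))
})

test_that("nested CV tests every sequence exactly once", {
  ds <- generate_dataset(generator_config(n_sequences = 20, seed = 3,
                                          domain_length_range = c(20L, 40L)))
  seen <- character(0)
  pipeline <- function(train, test) {
    seen <<- c(seen, vapply(test, `[[`, character(1), "id"))
    we <- window_dataset(test, 1)
    list(scores = rep(0.5, length(we$t)), labels = we$t)
  }
  res <- nested_cv(ds, 10, pipeline, seed = 4)
  expect_setequal(seen, vapply(ds, `[[`, character(1), "id"))
  expect_equal(nrow(res), 10L)
  # constant scorer gives exactly 0.5 under the ties rule
  expect_true(all(res$auroc[!res$flagged] == 0.5))
})

test_that("nested CV recovers a planted signal above chance", {
  ds <- generate_dataset(generator_config(
    n_sequences = 25, seed = 41,
    domain_length_range = c(25L, 50L), hinge_length_range = c(2L, 6L),
    hinge_aa_probs = demo_hinge_probs()))
  pipe <- klr_pipeline(9, kernel_spec("linear"),
                       training_config(gamma = 0.1), seed = 2)
  res <- suppressWarnings(nested_cv(ds, 5, pipe, seed = 4))
  aur <- res$auroc[!res$flagged]
  se <- sd(aur) / sqrt(length(aur))
  expect_gt(mean(aur), 0.5 + 3 * se)
})

test_that("paired t-test matches the closed form", {
  expect_equal(paired_ttest(1:5, 1:5), 1)
  set.seed(2)
  b <- runif(10)
  a <- b + 0.1 + rnorm(10, 0, 0.02)
  d <- a - b
  tstat <- mean(d) / (sd(d) / sqrt(10))
  expect_equal(paired_ttest(a, b), 2 * pt(-abs(tstat), df = 9),
               tolerance = 1e-12)
  expect_equal(paired_ttest(c(0.6, 0.62), c(0.5, 0.51)),
               2 * pt(-abs(mean(c(0.1, 0.11)) /
                             (sd(c(0.1, 0.11)) / sqrt(2))), df = 1),
               tolerance = 1e-12)
  expect_error(paired_ttest(c(1, 2), c(0.5, 1.5)), "degenerate")
})

test_that("imbalance sweep keeps the test set untouched", {
  ds <- generate_dataset(generator_config(
    n_sequences = 16, seed = 9, domain_length_range = c(25L, 50L),
    hinge_aa_probs = demo_hinge_probs()))
  sp <- split_train_test(ds, 0.25, seed = 1)
  pipe <- klr_pipeline(9, kernel_spec("linear"),
                       training_config(gamma = 0.1), seed = 3)
  tab <- imbalance_sweep(sp$train, sp$test, c(1, 5, 9), pipe)
  expect_equal(tab$neg_per_pos, c(1, 5, 9))
  expect_true(all(is.finite(tab$auroc)))
  # robustness: spread across ratios stays small
  expect_lt(max(tab$auroc) - min(tab$auroc), 0.05)
  expect_equal(nrow(imbalance_sweep(sp$train, sp$test, numeric(0), pipe)),
               0L)
})
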