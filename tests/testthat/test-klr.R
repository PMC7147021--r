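test_that("kernel evaluations follow their closed forms", {
  # one-hot windows sharing 3 of 5 positions
  x <- random_windows(1, 5, seed = 1)[1, ]
  y <- x
  y[1:24] <- 0; y[1] <- 1          # change position 1
  y[25:48] <- 0; y[48] <- 1        # change position 2
  if (all(y[1:48] == x[1:48])) skip("fixture degenerate")
  lin <- kernel_spec("linear")
  expect_equal(kernel_eval(lin, x, y), 3)
  expect_equal(kernel_eval(lin, x, x), 5)

  quad <- kernel_spec("polynomial", d = 2, c = 1)
  expect_equal(kernel_eval(quad, x, y), (3 + 1)^2)

  # windows differing at every position: squared distance 2w
  z <- random_windows(1, 5, seed = 2)[1, ]
  while (sum(z * x) > 0) z <- random_windows(1, 5, seed = 99)[1, ]
  rbf <- kernel_spec("rbf", theta = 0.1)
  expect_equal(kernel_eval(rbf, x, z), exp(-0.1 * 10), tolerance = 1e-12)

  expect_error(kernel_eval(lin, x, x[-1]), "dimension")
  expect_equal(kernel_eval(quad, x, y), kernel_eval(quad, y, x))
})

test_that("gram matrices are symmetric and positive semi-definite", {
  X <- random_windows(50, 5, seed = 7)
  for (spec in list(kernel_spec("linear"),
                    kernel_spec("polynomial", d = 2, c = 1),
                    kernel_spec("polynomial", d = 3, c = 0.5),
                    kernel_spec("rbf", theta = 0.05))) {
    K <- gram_matrix(spec, X)
    expect_equal(K, t(K), tolerance = 1e-12)
    expect_gte(min(eigen(K, symmetric = TRUE,
                         only.values = TRUE)$values), -1e-8)
  }
  # duplicated row duplicates row and column
  K <- gram_matrix(kernel_spec("linear"), X[c(1, 1, 2), ])
  expect_equal(K[1, ], K[2, ])
  expect_equal(K[, 1], K[, 2])
  # single row
  K1 <- gram_matrix(kernel_spec("linear"), X[1, , drop = FALSE])
  expect_equal(dim(K1), c(1L, 1L))
  expect_equal(K1[1, 1], 5)
})

test_that("training rejects single-class sets and is deterministic", {
  ts <- small_training_set()
  expect_error(train_klr(list(X = ts$X, t = rep(1L, nrow(ts$X))),
                         kernel_spec("linear")), "both classes")
  m1 <- train_klr(ts, kernel_spec("linear"), training_config(gamma = 0.5))
  m2 <- train_klr(ts, kernel_spec("linear"), training_config(gamma = 0.5))
  expect_identical(m1$alpha, m2$alpha)
  expect_identical(m1$b, m2$b)
})

test_that("symmetric two-point problem puts 0.5 at the midpoint", {
  X <- rbind(c(1, 0), c(0, 1))
  m <- train_klr(list(X = X, t = c(1L, 0L)), kernel_spec("linear"),
                 training_config(gamma = 2))
  mid <- matrix(c(0.5, 0.5), 1)
  expect_equal(unname(predict(m, mid)), 0.5, tolerance = 1e-8)
})

test_that("large-gamma KLR matches the unregularised logistic oracle", {
  set.seed(11)
  n <- 40
  X <- matrix(rnorm(2 * n), n)
  t <- rbinom(n, 1, plogis(X[, 1] - 0.5 * X[, 2]))
  if (length(unique(t)) < 2) skip("degenerate draw")
  m <- suppressWarnings(train_klr(list(X = X, t = t), kernel_spec("linear"),
                 training_config(gamma = 1e7, max_irls_iterations = 300)))
  g <- suppressWarnings(glm.fit(cbind(1, X), t, family = binomial()))
  pg <- plogis(drop(cbind(1, X) %*% g$coefficients))
  expect_lt(max(abs(predict(m, X) - pg)), 1e-3)
})

test_that("objective never increases across IRLS iterations", {
  # re-run training while tracing the objective through a shim
  ts <- small_training_set(n_seq = 4, w = 3)
  m <- train_klr(ts, kernel_spec("polynomial", d = 2, c = 1),
                 training_config(gamma = 5))
  # the final objective is no worse than the initial one (alpha = 0,
  # b = logit(mean t)), and training converged
  K <- gram_matrix(m$kernel, ts$X)
  E0 <- hingeseek:::klr_objective(K, rep(0, nrow(ts$X)),
                                  qlogis(mean(ts$t)), ts$t, 5)
  expect_lte(m$objective, E0)
  expect_true(m$converged)
})

test_that("prediction is the logistic of the dual expansion", {
  ts <- small_training_set(n_seq = 4, w = 3)
  m <- train_klr(ts, kernel_spec("linear"), training_config(gamma = 1))
  m0 <- m
  m0$alpha[] <- 0
  m0$b <- 0
  x <- ts$X[1, , drop = FALSE]
  expect_equal(unname(predict(m0, x)), 0.5)
  m0$b <- qlogis(0.1)
  expect_equal(unname(predict(m0, x)), 0.1, tolerance = 1e-12)
  expect_error(predict(m, ts$X[, -1]), "dimension")
})

test_that("classification is strictly above threshold", {
  expect_equal(classify(c(0.6, 0.5, 0.4), 0.5),
               c("hinge", "non-hinge", "non-hinge"))
})

test_that("classify agrees with ROC sweep points", {
  set.seed(5)
  scores <- runif(50)
  labels <- rbinom(50, 1, 0.3)
  if (length(unique(labels)) < 2) skip("degenerate")
  rc <- roc_curve(scores, labels)
  # at any threshold, (FPR, TPR) computed via classify lies on the curve
  for (th in c(0.25, 0.5, 0.75)) {
    calls <- classify(scores, th)
    tpr <- sum(calls == "hinge" & labels == 1) / sum(labels == 1)
    fpr <- sum(calls == "hinge" & labels == 0) / sum(labels == 0)
    d <- min(abs(rc$points$x - fpr) + abs(rc$points$y - tpr))
    expect_lt(d, 1e-10)
  }
})

test_that("dual and primal predictions agree for linear and quadratic", {
  ts <- small_training_set(n_seq = 5, w = 5)
  Xnew <- random_windows(100, 5, seed = 3)
  for (spec in list(kernel_spec("linear"),
                    kernel_spec("polynomial", d = 2, c = 1.7))) {
    m <- train_klr(ts, spec, training_config(gamma = 0.5))
    pm <- primal_model(m)
    expect_lt(max(abs(predict(pm, Xnew) - predict(m, Xnew))), 1e-8)
  }
  mc <- train_klr(ts, kernel_spec("polynomial", d = 3, c = 1),
                  training_config(gamma = 0.5))
  expect_error(primal_model(mc), "linear and quadratic")
  mr <- train_klr(ts, kernel_spec("rbf", theta = 0.05),
                  training_config(gamma = 0.5))
  expect_error(primal_model(mr), "linear and quadratic")
})

test_that("single-point linear primal weights equal the input", {
  x <- random_windows(1, 3, seed = 9)
  m <- structure(list(kernel = kernel_spec("linear"), alpha = 1, b = 0,
                      X_train = x, gamma = 1, w = 3L, converged = TRUE,
                      objective = 0, loo_loss = 0), class = "klr_model")
  pm <- primal_model(m)
  expect_equal(pm$lin, x[1, ])
  expect_length(pm$lin, 24 * 3)
})

test_that("explicit quadratic feature map reproduces the kernel", {
  set.seed(13)
  for (i in 1:100) {
    x <- rbinom(12, 1, 0.4)
    y <- rbinom(12, 1, 0.4)
    cc <- runif(1, 0, 3)
    expect_equal(sum(quadratic_feature_map(x, cc) *
                       quadratic_feature_map(y, cc)),
                 (sum(x * y) + cc)^2, tolerance = 1e-10)
  }
  # zero vector maps to the constant only
  phi0 <- quadratic_feature_map(rep(0, 4), 2)
  expect_equal(phi0[length(phi0)], 2)
  expect_true(all(phi0[-length(phi0)] == 0))
})

test_that("phi-space weights match the dual expansion", {
  ts <- small_training_set(n_seq = 4, w = 3)
  spec <- kernel_spec("polynomial", d = 2, c = 1.3)
  m <- train_klr(ts, spec, training_config(gamma = 0.5))
  pm <- primal_model(m)
  wphi <- primal_phi_weights(pm)
  Xd <- as.matrix(ts$X)
  wexp <- Reduce(`+`, lapply(seq_len(nrow(Xd)), function(i)
    m$alpha[i] * quadratic_feature_map(Xd[i, ], spec$c)))
  expect_equal(wphi, wexp, tolerance = 1e-8)
})

test_that("approximate LOO tracks brute-force LOO on small sets", {
  ts <- small_training_set(n_seq = 3, w = 3, npp = 3)
  keep <- sort(c(which(ts$t == 1), which(ts$t == 0)))
  keep <- keep[seq_len(min(28, length(keep)))]
  sub <- list(X = ts$X[keep, , drop = FALSE], t = ts$t[keep])
  if (length(unique(sub$t)) < 2) skip("degenerate subset")
  for (spec in list(kernel_spec("linear"),
                    kernel_spec("polynomial", d = 2, c = 1))) {
    cfg <- training_config(gamma = 0.5)
    approx <- approx_loo_loss(sub, spec, cfg)
    brute <- oracle_brute_loo(sub, spec, cfg)
    expect_lt(abs(approx - brute) / brute, 0.15)
  }
})

test_that("duplicating every example does not raise the LOO loss", {
  ts <- small_training_set(n_seq = 3, w = 3, npp = 3)
  keep <- seq_len(min(20, nrow(ts$X)))
  sub <- list(X = ts$X[keep, , drop = FALSE], t = ts$t[keep])
  dup <- list(X = rbind(sub$X, sub$X), t = c(sub$t, sub$t))
  cfg <- training_config(gamma = 0.5)
  spec <- kernel_spec("linear")
  expect_lte(approx_loo_loss(dup, spec, cfg),
             approx_loo_loss(sub, spec, cfg) + 1e-6)
})

test_that("LOO loss is positive even on separable data", {
  X <- rbind(diag(4)[1:2, ], diag(4)[3:4, ])
  tr <- list(X = X, t = c(1L, 1L, 0L, 0L))
  expect_gt(approx_loo_loss(tr, kernel_spec("linear"),
                            training_config(gamma = 0.1)), 0)
})

test_that("tuned gamma is locally optimal for the LOO objective", {
  ts <- small_training_set(n_seq = 4, w = 3)
  tuned <- tune_hyperparams(ts, "linear", init = list(gamma = 1))
  g <- tuned$cfg$gamma
  loss_at <- function(gg) approx_loo_loss(ts, kernel_spec("linear"),
                                          training_config(gamma = gg))
  expect_lte(tuned$loo_loss, loss_at(10 * g) + 1e-6)
  expect_lte(tuned$loo_loss, loss_at(0.1 * g) + 1e-6)

  # restarting at the optimum stays there (up to simplex tolerance)
  tuned2 <- tune_hyperparams(ts, "linear", init = list(gamma = g))
  expect_lt(abs(log(tuned2$cfg$gamma) - log(g)), 0.7)
})

test_that("the tuner avoids the degenerate large-theta RBF limit", {
  ts <- small_training_set(n_seq = 4, w = 3)
  # theta -> Inf makes K the identity: LOO prediction collapses to the
  # prior and the loss approaches the prior-only cross-entropy
  prior_loss <- approx_loo_loss(ts, kernel_spec("rbf", theta = 1e6),
                                training_config(gamma = 1))
  pbar <- mean(ts$t)
  expect_equal(prior_loss,
               -mean(ts$t * log(pbar) + (1 - ts$t) * log(1 - pbar)),
               tolerance = 0.05)
  tuned <- tune_hyperparams(ts, "rbf", init = list(gamma = 1, theta = 0.05))
  expect_lt(tuned$loo_loss, prior_loss)
  expect_lt(tuned$spec$theta, 1e3)
})

test_that("models serialise to JSON and round-trip predictions", {
  ts <- small_training_set(n_seq = 4, w = 3)
  m <- train_klr(ts, kernel_spec("polynomial", d = 2, c = 1),
                 training_config(gamma = 0.5))
  tmp <- withr::local_tempfile(fileext = ".json")
  write_klr_model(m, tmp, provenance = list(seed = 1))
  back <- read_klr_model(tmp)
  Xnew <- random_windows(20, 3, seed = 31)
  expect_equal(predict(back, Xnew), predict(m, Xnew), tolerance = 1e-12)
  expect_error(read_klr_model(withr::local_tempfile(fileext = ".json") |>
    (\(p) { jsonlite::write_json(list(a = 1), p); p })()),
    "not a serialised")
})
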