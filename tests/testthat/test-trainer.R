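test_that("model builders have the advertised shapes and seeded init", {
  m <- build_model("linear", input_dim = 7, K = 5, seed = 3)
  expect_equal(length(m$params$W) + length(m$params$b), 7 * 5 + 5)
  m2 <- build_model("linear", input_dim = 7, K = 5, seed = 3)
  expect_identical(m$params, m2$params)
  X <- matrix(rnorm(21), 3, 7)
  Z <- ordsmooth:::.forward(m, X)$Z
  expect_equal(dim(Z), c(3L, 5L))
  net <- build_model("small_net", input_dim = 7, K = 5, hidden = 6, seed = 1)
  expect_equal(dim(ordsmooth:::.forward(net, X)$Z), c(3L, 5L))
  expect_error(build_model("linear", input_dim = 0, K = 5), "shape")
})

test_that("hard-scheme training minimizes ordinary cross-entropy", {
  # per-batch: the soft loss with one-hot targets equals standard CE
  set.seed(51)
  P <- softmax(matrix(rnorm(40), 8, 5))
  y <- sample(0:4, 8, replace = TRUE)
  Q <- encode_batch(y, 5, smoothing_config("hard"))
  expect_equal(batch_loss(P, Q),
               mean(-log(P[cbind(1:8, y + 1)])), tolerance = 1e-15)
})

test_that("a linear model learns separable noiseless vector data", {
  cfg <- synthetic_config(n_samples = 600, severity_noise_sd = 0.15,
                          prevalence = c(0.4, 0.2, 0.2, 0.1, 0.1), seed = 52)
  ds <- simulate_dataset(cfg)
  tr <- ds$split == "train"; va <- ds$split == "val"
  tc <- train_config(learning_rate = 0.05, max_epochs = 60, patience = 10,
                     seed = 52)
  m <- build_model("linear", cfg$feature_dim, 5, seed = 52)
  fit <- train_model(m, ds$features[tr, ], ds$clean_grades[tr],
                     ds$features[va, ], ds$clean_grades[va], tc)
  # loss decreases over the first epochs
  expect_lt(fit$history$train_loss[5], fit$history$train_loss[1])
  tab <- predict_scores(fit, ds$features[tr, ], ds$ids[tr],
                        ds$clean_grades[tr])
  acc <- mean(tab$y_pred == tab$y_true)
  expect_gt(acc, 0.95)
  # independent oracle: a converged multinomial logistic fit on the same
  # data should also be near-perfect, confirming separability
  skip_if_not_installed("nnet")
  or <- nnet::multinom(y ~ ., data = data.frame(y = factor(ds$clean_grades[tr]),
                                                ds$features[tr, ]),
                       trace = FALSE, maxit = 300)
  acc_oracle <- mean(predict(or) == factor(ds$clean_grades[tr]))
  expect_gt(acc_oracle, 0.95)
})

test_that("early stopping keeps the best epoch and obeys patience", {
  cfg <- synthetic_config(n_samples = 500, seed = 53,
                          prevalence = c(0.4, 0.2, 0.2, 0.1, 0.1))
  ds <- simulate_dataset(cfg)
  tr <- ds$split == "train"; va <- ds$split == "val"
  tc <- train_config(max_epochs = 50, patience = 0, seed = 53)
  m <- build_model("linear", cfg$feature_dim, 5, seed = 53)
  fit <- train_model(m, ds$features[tr, ], ds$noisy_grades[tr],
                     ds$features[va, ], ds$noisy_grades[va], tc)
  h <- fit$history$val_loss
  n_ep <- length(h)
  expect_equal(fit$stopped_epoch, n_ep)
  if (n_ep < 50) {
    # every epoch before the stop improved on the best so far ...
    improving <- h[seq_len(n_ep - 1)]
    expect_true(all(improving == cummin(improving)))
    expect_true(all(diff(improving) < 0))
    # ... and the stopping epoch is the first non-improvement
    expect_gte(h[n_ep], min(improving))
    expect_equal(fit$best_epoch, n_ep - 1L)
  }
  # best epoch holds the minimal monitored value
  expect_equal(h[fit$best_epoch], min(h))
})

test_that("training history is bit-reproducible under a fixed seed", {
  cfg <- synthetic_config(n_samples = 300, seed = 54,
                          prevalence = c(0.4, 0.2, 0.2, 0.1, 0.1))
  ds <- simulate_dataset(cfg)
  tr <- ds$split == "train"; va <- ds$split == "val"
  tc <- train_config(max_epochs = 5, label_scheme = smoothing_config("nuls"),
                     seed = 54)
  run <- function() {
    m <- build_model("linear", cfg$feature_dim, 5, seed = 54)
    train_model(m, ds$features[tr, ], ds$noisy_grades[tr],
                ds$features[va, ], ds$noisy_grades[va], tc)
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
})

test_that("predicted score tables are normalized and shape-checked", {
  m <- build_model("linear", 4, 5, seed = 1)
  m$scaler <- list(center = rep(0, 4), scale = rep(1, 4))
  X <- matrix(rnorm(12), 3, 4)
  tab <- predict_scores(m, X, paste0("s", 1:3), c(0L, 1L, 2L))
  expect_true(all(abs(rowSums(tab$scores) - 1) < 1e-9))
  tab_dup <- predict_scores(m, X[c(1, 1), ], c("a", "b"), c(0L, 0L))
  expect_equal(tab_dup$scores[1, ], tab_dup$scores[2, ])
  empty <- predict_scores(m, matrix(0, 0, 4), character(0), integer(0))
  expect_equal(length(empty$y_true), 0L)
  expect_error(predict_scores(m, matrix(0, 2, 3), c("a", "b"), c(0L, 0L)),
               "dimension")
})

test_that("non-finite losses abort with a diagnostic", {
  cfg <- synthetic_config(n_samples = 300, seed = 55,
                          prevalence = c(0.4, 0.2, 0.2, 0.1, 0.1))
  ds <- simulate_dataset(cfg)
  tr <- ds$split == "train"; va <- ds$split == "val"
  tc <- train_config(max_epochs = 3, patience = 1, seed = 55)
  m <- build_model("linear", cfg$feature_dim, 5, seed = 55)
  bad <- ds$features[tr, ]
  bad[1, 1] <- NaN  # corrupt input propagates to the loss
  expect_error(train_model(m, bad, ds$noisy_grades[tr],
                           ds$features[va, ], ds$noisy_grades[va], tc),
               "non-finite")
})
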