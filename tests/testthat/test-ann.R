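test_that("network initialization is seeded and produces small weights", {
  a <- init_network(7, 10, seed = 4)
  b <- init_network(7, 10, seed = 4)
  expect_identical(a$W1, b$W1)
  expect_identical(a$w2, b$w2)
  c <- init_network(7, 10, seed = 5)
  expect_false(identical(a$W1, c$W1))

  # zero weights: output is logistic(bias) everywhere
  z <- a
  z$W1[] <- 0; z$b1[] <- 0; z$w2[] <- 0; z$b2 <- 0.3
  expect_equal(unname(predict(z, matrix(rnorm(70), 10, 7))),
               rep(plogis(0.3), 10), tolerance = 1e-12)
})

test_that("forward pass matches a hand-computed 2-2-1 network", {
  net <- init_network(2, 2, seed = 1)
  net$W1 <- matrix(c(0.5, -0.3, 0.2, 0.8), 2, 2)
  net$b1 <- c(0.1, -0.2)
  net$w2 <- c(1.5, -0.7)
  net$b2 <- 0.25
  x <- c(0.4, -1.2)
  z1 <- tanh(0.5 * 0.4 + 0.2 * (-1.2) + 0.1)
  z2 <- tanh(-0.3 * 0.4 + 0.8 * (-1.2) - 0.2)
  expected <- plogis(1.5 * z1 - 0.7 * z2 + 0.25)
  expect_equal(unname(predict(net, x)), expected, tolerance = 1e-12)
})

test_that("prediction is pure, bounded and dimension-checked", {
  net <- init_network(5, 10, seed = 2)
  X <- withr::with_seed(3, matrix(rnorm(5e4), 1e4, 5))
  s1 <- predict(net, X)
  s2 <- predict(net, X)
  expect_identical(s1, s2)
  expect_true(all(s1 >= 0 & s1 <= 1))
  expect_error(predict(net, matrix(0, 3, 4)), class = "flimglia_error_value")
})

test_that("constant targets are learned to near-zero error", {
  X <- withr::with_seed(4, matrix(rnorm(400), 100, 4))
  tbl <- make_feature_table(X, rep(0, 100))
  spl <- tibble::tibble(row = 1:100,
                        split = factor(rep(c("train", "validation", "test"),
                                           c(70, 15, 15)),
                                       levels = c("train", "validation", "test")))
  fit <- train_network(init_network(4, 10, seed = 1), tbl, spl, seed = 1)
  expect_lt(fit$report$mse_test, 1e-3)
})

test_that("the network learns XOR for most seeds", {
  X <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))[rep(1:4, 3), ]
  y <- rep(c(0, 1, 1, 0), 3)
  tbl <- make_feature_table(X, y)
  spl <- tibble::tibble(row = 1:12,
                        split = factor(rep(c("train", "validation", "test"),
                                           each = 4),
                                       levels = c("train", "validation", "test")))
  ok <- sum(vapply(1:10, function(s) {
    fit <- train_network(init_network(2, 10, seed = s), tbl, spl,
                         regularization = "fixed", lambda = 1e-6,
                         max_epochs = 500, seed = s)
    fit$report$mse_train < 0.05
  }, logical(1)))
  expect_gte(ok, 8)
})

test_that("well-separated Gaussian classes reach near-zero test MSE", {
  withr::with_seed(11, {
    n <- 2000
    y <- rbinom(n, 1, 0.5)
    X <- matrix(rnorm(n * 7), n, 7) + 3 * y  # class means 3 sd apart
  })
  tbl <- make_feature_table(X, y)
  spl <- split_dataset(tbl, seed = 12)
  nrm <- normalize_features(tbl)
  fit <- train_network(init_network(7, 10, seed = 13), nrm$table, spl,
                       stats = nrm$stats, seed = 13)
  expect_lt(fit$report$mse_test, 0.05)
  # beats the best constant predictor by at least 5x
  p <- mean(y)
  expect_lt(fit$report$mse_test, p * (1 - p) / 5)
})

test_that("growing the weight penalty shrinks weights toward a constant output", {
  withr::with_seed(21, {
    y <- rbinom(500, 1, 0.5)
    X <- matrix(rnorm(500 * 3), 500, 3) + 2 * y
  })
  tbl <- make_feature_table(X, y)
  spl <- split_dataset(tbl, seed = 22)
  norms <- vapply(c(1e-4, 1e-2, 1, 100), function(lam) {
    fit <- train_network(init_network(3, 10, seed = 23), tbl, spl,
                         regularization = "fixed", lambda = lam,
                         max_epochs = 80, seed = 23)
    sqrt(sum(flimglia:::weights_to_vec(fit$net)^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))

  # at the largest penalty the output is nearly constant
  fit_big <- train_network(init_network(3, 10, seed = 23), tbl, spl,
                           regularization = "fixed", lambda = 100,
                           max_epochs = 80, seed = 23)
  preds <- predict(fit_big, tbl)
  expect_lt(diff(range(preds)), 0.05)
})

test_that("Bayesian regularization reports a plausible evidence state", {
  withr::with_seed(31, {
    y <- rbinom(600, 1, 0.5)
    X <- matrix(rnorm(600 * 4), 600, 4) + 2.5 * y
  })
  tbl <- make_feature_table(X, y)
  spl <- split_dataset(tbl, seed = 32)
  fit <- train_network(init_network(4, 10, seed = 33), tbl, spl, seed = 33)
  r <- fit$report
  expect_gt(r$alpha, 0)
  expect_gt(r$beta, 0)
  nw <- flimglia:::n_weights(fit$net)
  expect_true(r$gamma > 0 && r$gamma <= nw)
  expect_true(all(c(r$mse_train, r$mse_validation, r$mse_test) >= 0))
})

test_that("models round-trip through JSON with identical predictions", {
  withr::with_seed(41, {
    y <- rbinom(300, 1, 0.4)
    X <- matrix(rnorm(300 * 7), 300, 7) + 2 * y
  })
  tbl <- make_feature_table(X, y)
  nrm <- normalize_features(tbl)
  fit <- train_network(init_network(7, 10, seed = 42), nrm$table,
                       split_dataset(tbl, seed = 42), stats = nrm$stats,
                       max_epochs = 20, seed = 42)
  f <- file.path(withr::local_tempdir(), "model.json")
  save_model(fit, f)
  back <- load_model(f)
  Xnew <- withr::with_seed(43, matrix(rnorm(700), 100, 7))
  expect_equal(predict(back, Xnew), predict(fit$net, Xnew), tolerance = 1e-12)

  # wrong input width is rejected (an FBM-sized model never accepts decays)
  expect_error(predict(back, matrix(0, 2, 256)), class = "flimglia_error_value")

  # corrupted payloads and foreign versions are rejected by name
  bad <- file.path(withr::local_tempdir(), "bad.json")
  writeLines("{not json", bad)
  expect_error(load_model(bad), class = "flimglia_error_format")
  v <- jsonlite::read_json(f)
  v$version <- "99"
  jsonlite::write_json(v, bad, auto_unbox = TRUE)
  expect_error(load_model(bad), "99", class = "flimglia_error_format")
})

test_that("tidiers expose weights and the training report", {
  fit <- train_network(init_network(3, 4, seed = 2),
                       make_feature_table(matrix(rnorm(60), 20, 3),
                                          rep(0:1, 10)),
                       tibble::tibble(row = 1:20,
                                      split = factor(rep(c("train", "validation", "test"),
                                                         c(14, 3, 3)),
                                                     levels = c("train", "validation", "test"))),
                       max_epochs = 5, seed = 2)
  td <- tidy(fit)
  expect_equal(nrow(td), 3 * 4 + 4 + 4 + 1)
  expect_identical(glance(fit), fit$report)
})
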