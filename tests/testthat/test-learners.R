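fit_toy_rf <- function(num_trees, seed = 1, n = 200) {
  set.seed(3)
  x <- matrix(stats::rnorm(n * 3), n, 3,
              dimnames = list(NULL, c("f1", "f2", "f3")))
  y <- cbind(x[, 1] + 0.1 * stats::rnorm(n), -x[, 2])
  list(x = x, y = y,
       fit = movestates:::ml_fit(learner_rf(num_trees = num_trees), x, y,
                                 task = "mvreg", seed = seed))
}

test_that("a single-member ensemble samples its own prediction", {
  toy <- fit_toy_rf(num_trees = 1)
  set.seed(1)
  s <- sample_member_prediction(toy$fit, toy$x[1:5, ])
  p <- movestates:::ml_predict(toy$fit, toy$x[1:5, ])
  expect_equal(s, p)
})

test_that("member sampling is seeded and averages to the ensemble mean", {
  toy <- fit_toy_rf(num_trees = 25)
  xrow <- toy$x[1, , drop = FALSE]
  set.seed(11)
  a <- replicate(5, sample_member_prediction(toy$fit, xrow))
  set.seed(11)
  b <- replicate(5, sample_member_prediction(toy$fit, xrow))
  expect_identical(a, b)
  set.seed(12)
  draws <- replicate(3000, sample_member_prediction(toy$fit, xrow)[1, 1])
  ens <- movestates:::ml_predict(toy$fit, xrow)[1, 1]
  expect_equal(mean(draws), ens, tolerance = 3 * stats::sd(draws) /
                 sqrt(3000) / max(abs(ens), 1e-6))
})

test_that("Monte Carlo dropout draws honour the dropout probability", {
  set.seed(4)
  n <- 300
  x <- matrix(stats::rnorm(n * 4), n, 4)
  y <- factor(ifelse(x[, 1] + x[, 2] > 0, "a", "b"))
  net0 <- fit_mlp(x, y, head = "softmax", hidden = 8, dropout = 0,
                  epochs = 3, seed = 1)
  d1 <- mc_dropout_sample(net0, x[1:4, ])
  d2 <- mc_dropout_sample(net0, x[1:4, ])
  expect_identical(d1, d2) # p* = 0: deterministic
  net5 <- fit_mlp(x, y, head = "softmax", hidden = 16, dropout = 0.5,
                  epochs = 3, seed = 1)
  set.seed(5)
  draws <- replicate(400, mc_dropout_sample(net5, x[1, , drop = FALSE])[1, 1])
  expect_gt(stats::var(draws), 0)
  probs <- mc_dropout_sample(net5, x[1:50, ])
  expect_true(all(abs(rowSums(probs) - 1) < 1e-9))
  unfit <- net5
  unfit$fitted <- FALSE
  expect_error(mc_dropout_sample(unfit, x[1:2, ]), "not fitted")
})

test_that("the network learns a separable classification problem", {
  set.seed(1)
  n <- 500
  x <- matrix(stats::rnorm(n * 4), n, 4)
  y <- factor(ifelse(x[, 1] + x[, 2] > 0, "a", "b"))
  net <- fit_mlp(x, y, head = "softmax", hidden = 16, dropout = 0.1,
                 epochs = 40, lr = 5e-3, seed = 2)
  p <- predict(net, x)
  acc <- mean(colnames(p)[max.col(p)] == as.character(y))
  expect_gt(acc, 0.9)
})

test_that("the recurrent layer predicts a sequence a dense net cannot see", {
  t <- 1:400
  x <- matrix(sin(t / 10), ncol = 1)
  y <- matrix(sin((t + 1) / 10), ncol = 1)
  net <- fit_mlp(x, y, head = "linear", hidden = 16, dropout = 0,
                 epochs = 30, batch_size = 25, lr = 1e-2, recurrent = TRUE,
                 seed = 4)
  expect_lt(mean((predict(net, x) - y)^2), 0.05)
})

test_that("PCA reduction preserves variance accounting", {
  set.seed(6)
  base <- matrix(stats::rnorm(40), 20, 2)
  x <- base %*% matrix(stats::rnorm(10), 2, 5) # rank-2 data in 5 dims
  pc2 <- pca_reduce(x, 2)
  expect_equal(pc2$cum_var[2], 1, tolerance = 1e-9)
  expect_true(all(diff(pc2$cum_var) >= -1e-12))
  pc_full <- pca_reduce(x, 5)
  recon <- predict(pc_full, x) %*% t(pc_full$rotation)
  recon <- sweep(recon, 2, pc_full$center, "+")
  expect_equal(recon, x, tolerance = 1e-8)
  expect_error(pca_reduce(x, 6), "exceeds")
})

test_that("permutation importance isolates the generating predictor", {
  set.seed(8)
  n <- 400
  x <- matrix(stats::rnorm(n * 4), n, 4,
              dimnames = list(NULL, c("signal", "n1", "n2", "n3")))
  y <- cbind(3 * x[, "signal"] + 0.1 * stats::rnorm(n), stats::rnorm(n, 0, 0.1))
  fit <- movestates:::ml_fit(learner_rf(num_trees = 50), x, y,
                             task = "mvreg", seed = 1)
  imp <- variable_importance(fit, x, y, repeats = 3, seed = 2)
  expect_identical(imp$variable[1], "signal")
  noise_imp <- imp$importance[imp$variable != "signal"]
  expect_true(all(abs(noise_imp) < 0.2 * imp$importance[1]))
  expect_error(variable_importance(fit, x[1, , drop = FALSE],
                                   y[1, , drop = FALSE]), "more than one")
})
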