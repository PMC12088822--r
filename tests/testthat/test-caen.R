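test_that("softmax weights order inversely to losses and are shift invariant", {
  expect_equal(softmax_weights(c(1, 1, 1)), rep(1 / 3, 3))
  expect_equal(softmax_weights(c(0, log(2))), c(2 / 3, 1 / 3))
  set.seed(100)
  for (trial in 1:25) {
    L <- rnorm(3, sd = 2)
    w <- softmax_weights(L)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w > 0))
    # strict inverse ordering: L_i < L_j  =>  w_i > w_j
    expect_identical(order(w), order(-L))
    expect_equal(softmax_weights(L + 5.7), w, tolerance = 1e-12)
  }
  expect_error(softmax_weights(numeric(0)), "empty")
  expect_error(softmax_weights(c(1, Inf)), "finite")
})

test_that("aggregation is the convex combination of learner predictions", {
  set.seed(101)
  preds <- lapply(1:3, function(i) {
    p <- runif(10)
    cbind(p, 1 - p)
  })
  expect_equal(aggregate_predictions(preds, c(1, 0, 0)),
               preds[[1]], ignore_attr = TRUE)
  same <- aggregate_predictions(list(preds[[1]], preds[[1]]), c(0.3, 0.7))
  expect_equal(unclass(same), preds[[1]], ignore_attr = TRUE)
  w <- softmax_weights(c(0.2, 0.5, 0.9))
  agg <- aggregate_predictions(preds, w)
  expect_equal(rowSums(agg), rep(1, 10), tolerance = 1e-12)
  lo <- pmin(preds[[1]][, 1], preds[[2]][, 1], preds[[3]][, 1])
  hi <- pmax(preds[[1]][, 1], preds[[2]][, 1], preds[[3]][, 1])
  expect_true(all(agg[, 1] >= lo - 1e-12 & agg[, 1] <= hi + 1e-12))
  expect_error(aggregate_predictions(list(preds[[1]], preds[[1]][1:5, ]),
                                     c(0.5, 0.5)), "mismatch")
})

test_that("cross-entropy has the right closed forms and clipping behaviour", {
  y <- c(0, 1, 1, 0)
  perfect <- cbind(c(1, 0, 0, 1), c(0, 1, 1, 0))
  expect_equal(cross_entropy(y, perfect), 0, tolerance = 1e-10)
  uniform <- matrix(0.5, 4, 2)
  expect_equal(cross_entropy(y, uniform), log(2))
  wrong <- cbind(c(0, 1), c(1, 0))      # probability 0 on the true class
  expect_equal(cross_entropy(c(0, 1), wrong), -log(1e-12))
  expect_error(cross_entropy(integer(0), matrix(0.5, 0, 2)), "no samples")
})

test_that("total loss adds the scaled regularizer monotonically", {
  expect_equal(total_loss(1.3, c(2, 5), 0), 1.3)
  expect_equal(total_loss(1, 2, 1), 3)
  lams <- seq(0, 2, by = 0.25)
  vals <- vapply(lams, function(l) total_loss(0.7, c(1, 2), l), numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_error(total_loss(1, 1, -0.1), "nonnegative")
})

test_that("gradient-descent steps contract a quadratic and are linear", {
  w <- 1
  for (i in 1:50) w <- sgd_step(w, 2 * w, 0.1)
  expect_lt(abs(w), 1e-4)
  p <- list(a = matrix(1:4, 2), b = c(1, 1))
  g <- list(a = matrix(1, 2, 2), b = c(2, 0))
  expect_equal(sgd_step(p, g, 0), p, ignore_attr = TRUE)
  g2 <- list(a = matrix(3, 2, 2), b = c(1, 1))
  summed <- sgd_step(p, Map(`+`, g, g2), 0.1)
  twice <- sgd_step(sgd_step(p, g, 0.1), g2, 0.1)
  expect_equal(summed, twice)
  expect_error(sgd_step(1, NaN, 0.1), "non-finite")
})

fit_small_caen <- function(seed, learner_epochs = NULL, epochs = 6,
                           lr = 0.01) {
  spec <- synth_spec(n_samples = 500, n_numeric = 4, mean_separation = 2,
                     seed = seed)
  d <- synth_tabular(spec)
  sp <- stratified_split(d, seed = seed)
  cfg <- train_control(epochs = epochs, pretrain_epochs = 3, lr = lr,
                       decay_every = 50, optimizer = "adam", seed = seed)
  caen(design_matrix(sp$train), sp$train$labels,
       design_matrix(sp$valid), sp$valid$labels, config = cfg,
       layer_sizes = c(8, 4), hidden = c(16, 8), d_model = 8,
       learner_epochs = learner_epochs)
}

test_that("ensemble weight history is normalized and the Jensen bound holds at every iteration", {
  m <- fit_small_caen(110)
  for (h in m$history) {
    expect_equal(sum(h$weights), 1, tolerance = 1e-9)
    expect_lte(h$ensemble_ce, sum(h$weights * h$losses) + 1e-9)
  }
  expect_equal(coef(m), m$weights)
  s <- summary(m)
  expect_true(all(abs(rowSums(s$history[, grep("^w_", names(s$history))]) - 1)
                  < 1e-9))
})

test_that("a crippled learner receives the smallest ensemble weight", {
  wins <- 0
  for (s in 1:10) {
    m <- fit_small_caen(120 + s, learner_epochs = list(dense = 0),
                        epochs = 30, lr = 0.02)
    wins <- wins + (which.min(m$weights) == 2L)
  }
  expect_gte(wins, 9)
})

test_that("ensemble predictions aggregate with the stored weights and are deterministic", {
  m <- fit_small_caen(130)
  spec <- synth_spec(n_samples = 200, n_numeric = 4, mean_separation = 2,
                     seed = 131)
  d <- synth_tabular(spec)
  X <- design_matrix(d)
  probs <- predict(m, X)
  expect_equal(rowSums(probs), rep(1, 200), tolerance = 1e-9)
  expect_identical(unclass(probs), unclass(predict(m, X)))
  labels <- predict(m, X, type = "class")
  expect_identical(labels, as.integer(probs[, 2] > probs[, 1]))
  # degenerate single-dominant-weight model reproduces that learner
  m1 <- m
  m1$weights <- c(0, 1, 0)
  expect_identical(predict(m1, X, type = "class"),
                   as.integer(predict(m$learners$dense, X)[, 2] >
                                predict(m$learners$dense, X)[, 1]))
  expect_error(predict(m, X[, 1:2]), "mismatch")
})

test_that("recalibration loop reruns until the accuracy threshold or the iteration cap", {
  spec <- synth_spec(n_samples = 300, n_numeric = 2, mean_separation = 0.2,
                     seed = 140)
  d <- synth_tabular(spec)
  sp <- stratified_split(d, seed = 140)
  cfg <- train_control(epochs = 2, pretrain_epochs = 1, seed = 140)
  m <- caen(design_matrix(sp$train), sp$train$labels,
            design_matrix(sp$valid), sp$valid$labels, config = cfg,
            layer_sizes = 4, hidden = 4, d_model = 4,
            perf_threshold = 0.999, max_iter = 3, extra_epochs = 1)
  expect_equal(length(m$history), 3L)   # unattainable threshold -> cap
  expect_equal(length(fit_small_caen(141)$history), 1L)  # default: one round
})
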