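test_that("energy evaluates the bilinear form", {
  p <- rbm_params(2, 2)
  expect_equal(rbm_energy(c(1, 0), c(0, 1), p), 0)
  p1 <- rbm_params(1, 1); p1$W[1, 1] <- 1
  expect_equal(rbm_energy(1, 1, p1), -1)
  p2 <- random_small_rbm(3, 2, seed = 1)
  expect_equal(rbm_energy(c(0, 0, 0), c(1, 1), p2), -sum(p2$c))
  expect_error(rbm_energy(c(1, 0), c(1, 1), p1), "mismatch")
})

test_that("conditionals are factorial logistic units", {
  p <- rbm_params(3, 2)
  expect_equal(rbm_conditionals(c(1, 0, 1), p), c(0.5, 0.5))
  expect_equal(rbm_conditionals(c(1, 0), p, "visible_given_hidden"),
               rep(0.5, 3))
  p$c <- c(30, -30)
  pr <- rbm_conditionals(c(0, 0, 0), p)
  expect_gt(pr[1], 1 - 1e-9)
  expect_lt(pr[2], 1e-9)
  p2 <- random_small_rbm(4, 3, seed = 2, scale = 2)
  pr2 <- rbm_conditionals(rbinom(4, 1, 0.5), p2)
  expect_true(all(pr2 >= 0 & pr2 <= 1))
})

test_that("partition function and joint probabilities match hand enumeration", {
  expect_equal(rbm_partition(rbm_params(2, 1)), 8)
  p <- rbm_params(1, 1); p$W[1, 1] <- log(2)
  expect_equal(rbm_partition(p), 5)       # state weights 1, 1, 1, 2
  expect_equal(rbm_joint_probability(1, 1, p), 2 / 5)
  expect_equal(rbm_joint_probability(0, 0, rbm_params(1, 1)), 1 / 4)
  expect_error(rbm_partition(rbm_params(15, 10)), "too large")
})

test_that("joint probabilities normalize for random enumerable machines", {
  for (trial in 1:20) {
    p <- random_small_rbm(sample(2:4, 1), sample(2:4, 1), seed = trial)
    nv <- nrow(p$W); nh <- ncol(p$W)
    states_v <- hdbncaen:::all_states(nv)
    states_h <- hdbncaen:::all_states(nh)
    total <- 0
    for (i in seq_len(nrow(states_v)))
      for (j in seq_len(nrow(states_h)))
        total <- total + rbm_joint_probability(states_v[i, ], states_h[j, ], p)
    expect_equal(total, 1, tolerance = 1e-12)
  }
})

test_that("contrastive divergence has the exact expected update on the 1x1 machine", {
  p <- rbm_params(1, 1)
  expect_identical(cd_update(p, matrix(1), lr = 0, seed = 1)$W, p$W)
  # E[dW] = lr * (0.5 - 0.25) over the Gibbs-chain randomness
  lr <- 1
  n_rep <- 10000
  dw <- vapply(seq_len(n_rep), function(s)
    cd_update(p, matrix(1), k = 1, lr = lr, seed = s)$W[1, 1], numeric(1))
  se <- sd(dw) / sqrt(n_rep)
  expect_lt(abs(mean(dw) - 0.25), 3 * se)
  expect_error(cd_update(p, matrix(numeric(0), 0, 1)), "empty")
})

test_that("long-chain negative statistics reach the exact model expectations", {
  p <- random_small_rbm(3, 2, seed = 7, scale = 0.8)
  exact <- hdbncaen:::rbm_exact_moments(p)
  n_chain <- 2000
  set.seed(8)
  v0 <- matrix(rbinom(n_chain * 3, 1, 0.5), n_chain, 3)
  stats <- hdbncaen:::rbm_gibbs_stats(p, v0, k = 500, seed = 9)
  # per-entry Monte-Carlo standard error of the mean of v_i * p(h_j)
  prods <- stats$v_samples[, 1] * stats$h_probs[, 1]
  se <- sd(prods) / sqrt(n_chain)
  expect_lt(max(abs(stats$vh - exact$vh)), 6 * max(se, 0.005))
  expect_lt(max(abs(stats$v - exact$v)), 6 * max(se, 0.005))
})

test_that("CD-1 training increases the exact log-likelihood of a toy pattern set", {
  set.seed(10)
  V <- matrix(rbinom(32, 1, 0.5), 8, 4)   # 8 binary patterns
  p <- random_small_rbm(4, 3, seed = 11, scale = 0.01)
  ll0 <- rbm_loglik(p, V)
  set.seed(12)
  for (epoch in 1:200) p <- cd_update(p, V, k = 1, lr = 0.1)
  expect_gt(rbm_loglik(p, V), ll0)
})

test_that("exact-gradient ascent increases log-likelihood monotonically", {
  set.seed(13)
  V <- matrix(rbinom(24, 1, 0.5), 6, 4)
  p <- random_small_rbm(4, 2, seed = 14, scale = 0.1)
  lls <- numeric(30)
  for (i in 1:30) {
    lls[i] <- rbm_loglik(p, V)
    g <- hdbncaen:::rbm_exact_grad(p, V)
    p$W <- p$W + 0.05 * g$W
    p$b <- p$b + 0.05 * g$b
    p$c <- p$c + 0.05 * g$c
  }
  expect_true(all(diff(lls) > -1e-12))
})

test_that("layerwise pretraining reduces reconstruction error and is seeded", {
  spec <- synth_spec(n_samples = 300, n_numeric = 6, mean_separation = 2,
                     seed = 15)
  d <- synth_tabular(spec)
  X <- apply(design_matrix(d), 2, function(c) (c - min(c)) / (max(c) - min(c)))
  cfg <- train_control(pretrain_epochs = 1, lr_pretrain = 0.05, seed = 16)
  one_rbm <- pretrain_stack(X, 6, cfg)
  expect_length(one_rbm, 1)
  expect_equal(dim(one_rbm[[1]]$W), c(6L, 6L))
  expect_identical(pretrain_stack(X, c(5, 3), cfg), pretrain_stack(X, c(5, 3), cfg))
  improved <- 0
  for (s in 1:10) {
    cfg1 <- train_control(pretrain_epochs = 1, lr_pretrain = 0.05, seed = s)
    cfg10 <- train_control(pretrain_epochs = 12, lr_pretrain = 0.05, seed = s)
    e1 <- hdbncaen:::rbm_reconstruction_error(pretrain_stack(X, 5, cfg1)[[1]], X)
    e10 <- hdbncaen:::rbm_reconstruction_error(pretrain_stack(X, 5, cfg10)[[1]], X)
    improved <- improved + (e10 < e1)
  }
  expect_gte(improved, 9)
  expect_error(pretrain_stack(X, c(5, 0), cfg), "positive")
  expect_error(pretrain_stack(X * 5, 5, cfg), "\\[0, 1\\]")
})
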