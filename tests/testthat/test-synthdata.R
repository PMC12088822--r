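test_that("generators are deterministic under a fixed seed", {
  spec <- synth_spec(n_samples = 200, n_numeric = 3, n_categorical = 2,
                     mean_separation = 1, seed = 42)
  a <- synth_tabular(spec); b <- synth_tabular(spec)
  expect_identical(a, b)
  ts_spec <- synth_spec(n_samples = 50, n_numeric = 0, n_timeseries = 2,
                        ts_length = 6, seed = 42)
  expect_identical(synth_timeseries(ts_spec), synth_timeseries(ts_spec))
  m1 <- synth_mask_pair(32, 32, 0.1, seed = 7)
  expect_identical(m1, synth_mask_pair(32, 32, 0.1, seed = 7))
})

test_that("class prior and class-conditional means match the generating model", {
  spec <- synth_spec(n_samples = 10000, n_numeric = 2, class_prior = 0.3,
                     mean_separation = 0, seed = 3)
  d <- synth_tabular(spec)
  # binomial CI on the label-1 fraction
  expect_lt(abs(mean(d$labels) - 0.3), 3 * sqrt(0.3 * 0.7 / 10000))
  # zero separation: class-conditional means agree up to sampling noise
  gap <- abs(mean(d$features$num1[d$labels == 1]) -
               mean(d$features$num1[d$labels == 0]))
  expect_lt(gap, 0.1)
  spec2 <- synth_spec(n_samples = 20000, n_numeric = 1, mean_separation = 2,
                      seed = 4)
  d2 <- synth_tabular(spec2)
  gap2 <- mean(d2$features$num1[d2$labels == 1]) -
    mean(d2$features$num1[d2$labels == 0])
  expect_lt(abs(gap2 - 2), 0.1)
})

test_that("time-series channels follow the requested AR(1) dynamics", {
  lag1 <- function(spec) {
    d <- synth_timeseries(spec)
    X <- as.matrix(d$features) -
      outer(ifelse(d$labels == 1, spec$mean_separation / 2,
                   -spec$mean_separation / 2), rep(1, spec$ts_length))
    cor(as.vector(X[, -spec$ts_length]), as.vector(X[, -1]))
  }
  white <- synth_spec(n_samples = 10000, n_numeric = 0, n_timeseries = 1,
                      ts_length = 10, ar_coefficient = 0,
                      mean_separation = 0, seed = 5)
  expect_lt(abs(lag1(white)), 0.05)
  persistent <- synth_spec(n_samples = 10000, n_numeric = 0, n_timeseries = 1,
                           ts_length = 10, ar_coefficient = 0.9,
                           mean_separation = 0, seed = 6)
  expect_lt(abs(lag1(persistent) - 0.9), 0.05)
  expect_error(synth_spec(n_timeseries = 1, ar_coefficient = 1), "abs")
})

test_that("corruption injects missingness and IQR-detectable outliers without touching labels", {
  spec <- synth_spec(n_samples = 1000, n_numeric = 10, mean_separation = 0,
                     seed = 8)
  d <- synth_tabular(spec)
  expect_identical(corrupt_dataset(d, 0, 0, seed = 1), d)
  cd <- corrupt_dataset(d, missing_rate = 0.1, outlier_rate = 0, seed = 9)
  n_miss <- sum(is.na(as.matrix(cd$features)))
  expect_lt(abs(n_miss - 1000), 3 * sqrt(1e4 * 0.1 * 0.9))
  co <- corrupt_dataset(d, missing_rate = 0, outlier_rate = 0.02, seed = 10)
  for (nm in names(co$features)) {
    changed <- which(co$features[[nm]] != d$features[[nm]])
    if (length(changed) > 0)
      expect_true(all(flag_outliers(co$features[[nm]], "iqr")[changed]))
  }
  expect_identical(co$labels, d$labels)
  expect_identical(co$schema, d$schema)
})

test_that("mask pairs have the requested disagreement rate", {
  same <- synth_mask_pair(16, 16, flip_prob = 0, seed = 1)
  expect_equal(dice_coefficient(same$truth, same$pred), 1)
  opp <- synth_mask_pair(16, 16, flip_prob = 1, seed = 1)
  expect_equal(mean(opp$truth == opp$pred), 0)
  mp <- synth_mask_pair(256, 256, flip_prob = 0.1, seed = 2)
  dis <- mean(mp$truth != mp$pred)
  expect_lt(abs(dis - 0.1), 3 * sqrt(0.1 * 0.9 / 65536))
})

test_that("closed-form Bayes accuracy matches the normal-CDF formula and is attained by the true rule", {
  expect_equal(bayes_accuracy(synth_spec(n_numeric = 3, mean_separation = 0)),
               0.5)
  expect_equal(bayes_accuracy(synth_spec(n_numeric = 1, mean_separation = 2)),
               pnorm(1))
  expect_equal(bayes_accuracy(synth_spec(n_numeric = 4, mean_separation = 1)),
               pnorm(1))
  expect_error(bayes_accuracy(synth_spec(n_numeric = 2, n_categorical = 1)),
               "numeric-only")
  # a large sample classified by the generating rule attains the ceiling
  spec <- synth_spec(n_samples = 40000, n_numeric = 4, mean_separation = 1,
                     seed = 12)
  d <- synth_tabular(spec)
  yhat <- as.integer(rowSums(design_matrix(d)) > 0)
  acc <- mean(yhat == d$labels)
  expect_lt(abs(acc - bayes_accuracy(spec)), 2 * sqrt(0.84 * 0.16 / 40000))
})

test_that("invalid specifications are rejected", {
  expect_error(synth_spec(n_numeric = 0, n_categorical = 0, n_timeseries = 0),
               "at least one")
  expect_error(synth_spec(class_prior = 0), "class_prior")
  expect_error(synth_spec(mean_separation = -1), "mean_separation")
})
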