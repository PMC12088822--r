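make_ds <- function(feats, kinds, labels, levels = NULL) {
  labeled_dataset(feats, labels, feature_schema(names(feats), kinds, levels))
}

test_that("imputation fills numeric medians, categorical modes and KNN means, and is idempotent", {
  d <- make_ds(data.frame(num1 = c(1, NA, 3, 100),
                          cat1 = c("a", "a", "b", NA)),
               c("numeric", "nominal"), c(0, 1, 0, 1),
               list(NULL, c("a", "b")))
  out <- impute_missing(d)
  expect_equal(out$features$num1[2], 3)       # median of {1, 3, 100}
  expect_equal(out$features$cat1[4], "a")     # unique mode
  expect_identical(impute_missing(out)$features, out$features)
  # mode tie breaks toward the lexicographically smallest level
  tie <- make_ds(data.frame(c1 = c("b", "a", NA)), "nominal", c(0, 1, 0),
                 list(c("a", "b")))
  expect_equal(impute_missing(tie)$features$c1[3], "a")
  all_na <- make_ds(data.frame(x = c(NA_real_, NA_real_)), "numeric",
                    c(0, 1))
  expect_error(impute_missing(all_na), "'x'")
})

test_that("KNN imputation of time-series cells averages the nearest complete rows", {
  feats <- data.frame(ts1_t1 = c(0, 0, 10, NA), ts1_t2 = c(1, 1, 11, 1))
  d <- make_ds(feats, c("timeseries", "timeseries"), c(0, 0, 1, 0))
  out <- impute_missing(d, k = 2)
  # co-observed t2 value 1 is closest to rows 1 and 2 -> mean(0, 0)
  expect_equal(out$features$ts1_t1[4], 0)
})

test_that("outlier flags follow the z-score and IQR rules exactly", {
  x <- c(rep(1, 9), 11)                 # population sd 3, Z(11) = 3 exactly
  expect_false(any(flag_outliers(x, "zscore", 3)))
  expect_true(flag_outliers(x, "zscore", 2.99)[10])
  y <- c(1:8, 100)                      # Q1 = 3, Q3 = 7, bounds [-3, 13]
  expect_identical(which(flag_outliers(y, "iqr")), 9L)
  expect_error(flag_outliers(rep(2, 5), "zscore"), "constant")
  z <- rnorm(50)
  expect_false(flag_outliers(z, "zscore", 3)[which.min(abs(z - mean(z)))])
})

test_that("scaling maps training data to the canonical ranges and extends affinely", {
  s <- fit_scaler(c(0, 5, 10))
  expect_equal(scale_values(c(0, 5, 10), "minmax", s), c(0, 0.5, 1))
  expect_gt(scale_values(12, "minmax", s), 1)          # no clipping
  s2 <- fit_scaler(c(1, 2, 3))
  expect_equal(scale_values(c(1, 2, 3), "standard", s2),
               c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_error(scale_values(1, "minmax", fit_scaler(c(2, 2))), "degenerate")
})

test_that("encodings satisfy the one-hot and ordinal contracts", {
  m <- encode_categorical(c("a", "b"), "nominal", c("a", "b"))
  expect_equal(unname(m), rbind(c(1, 0), c(0, 1)))
  expect_true(all(rowSums(encode_categorical(
    sample(letters[1:4], 50, TRUE), "nominal", letters[1:4])) == 1))
  expect_equal(as.vector(encode_categorical(c("low", "high", "low"),
                                            "ordinal",
                                            c("low", "med", "high"))),
               c(0, 2, 0))
  expect_equal(unname(encode_categorical(c("a", "a"), "nominal", "a")),
               matrix(1, 2, 1))
  expect_error(encode_categorical("z", "nominal", c("a", "b")), "z")
})

test_that("PCA is an orthonormal projection that preserves variance", {
  set.seed(1)
  t <- rnorm(100)
  line <- cbind(t, 2 * t)               # collinear 2-d data
  p <- pca_reduce(line, 1)
  expect_equal(p$explained_variance[1] / p$total_variance, 1,
               tolerance = 1e-10)
  X <- matrix(rnorm(200), 40, 5)
  full <- pca_reduce(X, 5)
  expect_equal(max(abs(crossprod(full$W) - diag(5))), 0, tolerance = 1e-10)
  recon <- full$Z %*% t(full$W) + rep(1, 40) %o% full$center
  expect_equal(max(abs(recon - X)), 0, tolerance = 1e-8)
  expect_true(all(diff(full$explained_variance) <= 1e-12))
  expect_equal(sum(full$explained_variance), sum(apply(X, 2, var)),
               tolerance = 1e-10)
  expect_error(pca_reduce(line, 3), "rank|n_components")
})

test_that("chi-square score matches the margins-based formula", {
  expect_equal(chi_square_score(matrix(10, 2, 2)), 0)
  expect_equal(chi_square_score(rbind(c(20, 0), c(0, 20))), 40)
  set.seed(2)
  tab <- matrix(rpois(4, 20) + 1, 2, 2)
  expect_gte(chi_square_score(tab), 0)
  expect_error(chi_square_score(rbind(c(0, 0), c(5, 5))), "margin")
})

test_that("recursive feature elimination keeps the informative feature", {
  hits <- 0
  for (rep in 1:100) {
    set.seed(rep)
    y <- rbinom(120, 1, 0.5)
    X <- matrix(rnorm(120 * 5), 120, 5)
    X[, 1] <- X[, 1] + 3 * (y - 0.5)    # only feature 1 carries signal
    sel <- rfe_select(X, y, 1)
    hits <- hits + (sel == 1L)
  }
  expect_gte(hits, 95)
  X <- matrix(rnorm(60), 20, 3)
  expect_identical(rfe_select(X, rbinom(20, 1, 0.5), 3), 1:3)
  sel2 <- rfe_select(X, rbinom(20, 1, 0.5), 2)
  expect_identical(sel2, sort(unique(sel2)))
  expect_error(rfe_select(X, rbinom(20, 1, 0.5), 4), "exceeds")
})

test_that("BMI derivation and its guards", {
  expect_equal(derive_bmi(70, 1.75), 70 / 1.75^2)
  expect_equal(derive_bmi(100, 2), 25)
  expect_equal(derive_bmi(0, 1.8), 0)
  expect_error(derive_bmi(70, 0), "height")
})

test_that("image augmentation composes involutions and grows the set as promised", {
  img <- matrix(runif(64), 8, 8)
  flip <- augment_images(list(img), "flip", seed = 1)[[2]]
  expect_equal(augment_images(list(flip), "flip", seed = 1)[[2]], img)
  r <- img
  for (i in 1:4) r <- augment_images(list(r), "rotate", seed = 1)[[2]]
  expect_equal(r, img)
  noiseless <- augment_images(list(img), "noise", seed = 1, noise_sd = 0)
  expect_equal(noiseless[[2]], img)
  out <- augment_images(list(img, img), c("rotate", "flip", "crop", "noise"),
                        seed = 2)
  expect_length(out, 2 * 5)
  expect_error(augment_images(list(matrix(numeric(0), 0, 0)), "flip"),
               "empty")
})

test_that("stratified splitting hits the 70/15/15 allocation exactly on balanced data", {
  spec <- synth_spec(n_samples = 1000, n_numeric = 2, class_prior = 0.5,
                     seed = 100)
  d <- synth_tabular(spec)
  # force exact balance for the canonical allocation check
  d$labels <- rep(c(0L, 1L), 500)
  sp <- stratified_split(d, seed = 1)
  expect_equal(vapply(sp$indices, length, integer(1)),
               c(train = 700L, valid = 150L, test = 150L))
  expect_equal(sum(sp$train$labels), 350)
  expect_equal(sum(sp$valid$labels), 75)
  expect_equal(sum(sp$test$labels), 75)
  all_idx <- sort(unlist(sp$indices, use.names = FALSE))
  expect_identical(all_idx, 1:1000)
  expect_identical(stratified_split(d, seed = 1)$indices, sp$indices)
  tiny <- make_ds(data.frame(x = rnorm(4)), "numeric", c(0, 0, 0, 1))
  expect_error(stratified_split(tiny), "at least 3")
})
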