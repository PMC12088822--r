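#' Impute missing cells
#'
#' Numeric columns receive the column median, categorical columns the mode
#' (ties broken toward the lexicographically smallest level), and time-series
#' columns the mean of the `k` nearest fully observed rows under Euclidean
#' distance on co-observed numeric and time-series values. Statistics may be
#' supplied pre-fitted (from the training split) via `params`.
#'
#' @param data a [labeled_dataset()].
#' @param k neighbours for KNN imputation of time-series cells.
#' @param params optional list of per-column imputation values fitted
#'   elsewhere; returned invisibly in attribute `"impute_params"`.
#' @return the dataset with no missing cells.
#' @export
impute_missing <- function(data, k = 5L, params = NULL) {
  stopifnot(inherits(data, "labeled_dataset"), is_count(k), k >= 1)
  feats <- data$features
  fitted <- if (is.null(params)) list() else params
  for (nm in names(feats)) {
    kind <- data$schema$kind[data$schema$name == nm]
    x <- feats[[nm]]
    if (all(is.na(x)))
      stop(sprintf("feature '%s' is fully missing; cannot impute", nm))
    if (kind == "numeric") {
      if (is.null(fitted[[nm]])) fitted[[nm]] <- stats::median(x, na.rm = TRUE)
      x[is.na(x)] <- fitted[[nm]]
    } else if (kind %in% c("nominal", "ordinal")) {
      if (is.null(fitted[[nm]])) {
        tab <- table(x)
        fitted[[nm]] <- sort(names(tab)[tab == max(tab)])[1]
      }
      x[is.na(x)] <- fitted[[nm]]
    }
    feats[[nm]] <- x
  }
  ts_cols <- data$schema$name[data$schema$kind == "timeseries"]
  if (length(ts_cols) > 0) {
    num_cols <- c(data$schema$name[data$schema$kind == "numeric"], ts_cols)
    X <- as.matrix(feats[num_cols])
    complete <- which(stats::complete.cases(X))
    need <- which(!stats::complete.cases(as.matrix(feats[ts_cols])))
    if (length(need) > 0 && length(complete) == 0)
      stop("no complete rows available for KNN imputation of time series")
    for (i in need) {
      obs <- !is.na(X[i, ])
      d2 <- colSums((t(X[complete, obs, drop = FALSE]) - X[i, obs])^2)
      nb <- complete[order(d2)[seq_len(min(k, length(complete)))]]
      for (nm in ts_cols) if (is.na(feats[[nm]][i]))
        feats[[nm]][i] <- mean(feats[[nm]][nb])
    }
  }
  out <- labeled_dataset(feats, data$labels, data$schema)
  attr(out, "impute_params") <- fitted
  out
}

#' Flag outliers by z-score or interquartile range
#'
#' The z-score rule flags |Z| > `z_threshold` with Z = (x - mean)/sd using the
#' population standard deviation and a strict inequality. The IQR rule flags
#' values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` with type-7 quartiles.
#'
#' @param x numeric vector (length >= 4 for `"iqr"`; non-constant for
#'   `"zscore"`).
#' @param method `"zscore"` or `"iqr"`.
#' @param z_threshold cutoff for the z-score rule.
#' @return logical vector of flags.
#' @export
flag_outliers <- function(x, method = c("zscore", "iqr"), z_threshold = 3) {
  method <- match.arg(method)
  stopifnot(is.numeric(x))
  if (method == "zscore") {
    s <- sqrt(mean((x - mean(x))^2))
    if (s == 0) stop("zscore outlier rule undefined for a constant vector")
    abs((x - mean(x)) / s) > z_threshold
  } else {
    if (length(x) < 4) stop("iqr rule needs at least 4 observations")
    q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    x < q[1] - 1.5 * iqr | x > q[2] + 1.5 * iqr
  }
}

#' Fit scaling parameters on training data
#'
#' @param x numeric training vector.
#' @return a `scaler_params` list with min, max, mean and population sd.
#' @export
fit_scaler <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 1)
  structure(list(min = min(x), max = max(x), mean = mean(x),
                 sd = sqrt(mean((x - mean(x))^2))),
            class = "scaler_params")
}

#' Scale a numeric vector with frozen parameters
#'
#' Min-max scaling maps the training range to `[0, 1]`; standardization
#' centers at the training mean with unit population variance. Values outside
#' the training range extend beyond `[0, 1]` (no clipping), so the transform
#' is affine everywhere.
#'
#' @param x numeric vector.
#' @param method `"minmax"` or `"standard"`.
#' @param params a [fit_scaler()] result (fitted on the training split).
#' @return scaled numeric vector.
#' @export
scale_values <- function(x, method = c("minmax", "standard"), params) {
  method <- match.arg(method)
  stopifnot(inherits(params, "scaler_params"))
  if (method == "minmax") {
    if (params$max == params$min)
      stop("degenerate feature: max equals min, min-max scaling undefined")
    (x - params$min) / (params$max - params$min)
  } else {
    if (params$sd == 0) stop("degenerate feature: zero variance")
    (x - params$mean) / params$sd
  }
}

#' Encode a categorical vector
#'
#' Nominal encoding produces one indicator column per level (no reference
#' level is dropped, so every row sums to 1); ordinal encoding maps levels to
#' integer ranks 0..K-1 in the supplied order.
#'
#' @param x character (or factor) vector.
#' @param kind `"nominal"` or `"ordinal"`.
#' @param levels complete ordered level vector.
#' @return numeric matrix (one column for ordinal).
#' @export
encode_categorical <- function(x, kind = c("nominal", "ordinal"), levels) {
  kind <- match.arg(kind)
  x <- as.character(x)
  unseen <- setdiff(unique(x), levels)
  if (length(unseen) > 0)
    stop(sprintf("unseen categor%s at transform time: %s",
                 if (length(unseen) > 1) "ies" else "y",
                 paste(unseen, collapse = ", ")))
  if (kind == "nominal") {
    m <- outer(x, levels, `==`) * 1
    colnames(m) <- levels
    m
  } else {
    matrix(match(x, levels) - 1, ncol = 1)
  }
}

#' Principal component reduction
#'
#' Centers the matrix, projects onto the leading eigenvectors of the
#' covariance matrix, and reports per-component explained variance. When
#' `n_components` is NULL the smallest number of components explaining at
#' least `var_target` of total variance is kept.
#'
#' @param X numeric matrix.
#' @param n_components components to keep, or NULL for the variance rule.
#' @param var_target explained-variance target used when `n_components` is
#'   NULL.
#' @return list with scores `Z`, loadings `W` (orthonormal columns),
#'   `explained_variance`, and the column `center` (for applying the frozen
#'   transform to new data: `scale(Xnew, center, FALSE) %*% W`).
#' @export
pca_reduce <- function(X, n_components = NULL, var_target = 0.95) {
  X <- as.matrix(X)
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  if (is.null(n_components)) {
    n_components <- which(cumsum(ev) / sum(ev) >= var_target)[1]
  }
  rank <- sum(ev > max(ev) * 1e-12)
  if (n_components > rank)
    stop(sprintf("n_components (%d) exceeds matrix rank (%d)",
                 n_components, rank))
  idx <- seq_len(n_components)
  list(Z = p$x[, idx, drop = FALSE], W = p$rotation[, idx, drop = FALSE],
       explained_variance = ev[idx], total_variance = sum(ev),
       center = p$center)
}

#' Chi-square statistic of a contingency table
#'
#' Pearson's statistic with expected counts from the row/column margins and no
#' continuity correction.
#'
#' @param observed matrix of nonnegative counts.
#' @return the chi-square statistic.
#' @export
chi_square_score <- function(observed) {
  observed <- as.matrix(observed)
  if (any(rowSums(observed) == 0) || any(colSums(observed) == 0))
    stop("zero row or column margin: expected counts undefined")
  unname(suppressWarnings(
    stats::chisq.test(observed, correct = FALSE)$statistic))
}

#' Recursive feature elimination
#'
#' Repeatedly fits a ridge-regularized linear scorer of the +/-1-coded label
#' on the standardized surviving features and drops the feature with the
#' smallest absolute coefficient until `n_keep` remain. Deterministic given
#' the data.
#'
#' @param X numeric matrix.
#' @param y binary labels.
#' @param n_keep number of features to retain.
#' @param ridge ridge penalty of the internal scorer.
#' @return sorted integer indices of the selected features.
#' @export
rfe_select <- function(X, y, n_keep, ridge = 1e-2) {
  X <- as.matrix(X)
  stopifnot(is_count(n_keep), n_keep >= 1)
  if (n_keep > ncol(X)) stop("n_keep exceeds the number of features")
  keep <- seq_len(ncol(X))
  yy <- ifelse(y == 1, 1, -1)
  while (length(keep) > n_keep) {
    Xs <- scale(X[, keep, drop = FALSE])
    Xs[is.nan(Xs)] <- 0
    beta <- solve(crossprod(Xs) + ridge * diag(length(keep)),
                  crossprod(Xs, yy))
    keep <- keep[-which.min(abs(beta))]
  }
  sort(keep)
}

#' Body mass index from weight and height
#'
#' @param weight_kg weight in kilograms (nonnegative).
#' @param height_m height in metres (positive).
#' @return BMI in kg/m^2.
#' @export
derive_bmi <- function(weight_kg, height_m) {
  if (any(height_m <= 0)) stop("height must be positive")
  if (any(weight_kg < 0)) stop("weight must be nonnegative")
  weight_kg / height_m^2
}

#' Augment grayscale image grids
#'
#' Each input image is kept and, per selected operation, one transformed copy
#' is appended: a 90-degree rotation, a horizontal flip, a random crop
#' re-padded with zeros to the original size, or additive Gaussian noise.
#'
#' @param images list of numeric matrices.
#' @param ops nonempty subset of `c("rotate", "flip", "crop", "noise")`.
#' @param seed integer seed for crop offsets and noise.
#' @param noise_sd standard deviation of the additive noise.
#' @return list of length `length(images) * (1 + length(ops))`.
#' @export
augment_images <- function(images, ops = c("rotate", "flip"), seed = 1L,
                           noise_sd = 0.05) {
  stopifnot(is.list(images), length(ops) >= 1,
            all(ops %in% c("rotate", "flip", "crop", "noise")))
  if (any(vapply(images, function(m) length(m) == 0, logical(1))))
    stop("empty image")
  rot90 <- function(m) t(m[nrow(m):1, , drop = FALSE])
  with_seed(derive_seed(seed, "augment"), {
    out <- images
    for (op in ops) {
      out <- c(out, lapply(images, function(m) {
        switch(op,
          rotate = rot90(m),
          flip = m[, ncol(m):1, drop = FALSE],
          crop = {
            h <- nrow(m); w <- ncol(m)
            ch <- max(1L, floor(h * 0.75)); cw <- max(1L, floor(w * 0.75))
            r0 <- sample.int(h - ch + 1L, 1L); c0 <- sample.int(w - cw + 1L, 1L)
            pad <- matrix(0, h, w)
            pad[seq_len(ch), seq_len(cw)] <-
              m[r0 + seq_len(ch) - 1L, c0 + seq_len(cw) - 1L]
            pad
          },
          noise = m + if (noise_sd > 0)
            matrix(stats::rnorm(length(m), sd = noise_sd), nrow(m)) else 0)
      }))
    }
    out
  })
}

#' Stratified train/validation/test split
#'
#' Rows of each class are permuted under the seed and allocated by flooring
#' the per-class target counts, with leftover rows assigned to train first,
#' then validation. Every part therefore matches the target class fractions
#' to within one row per class, and the parts partition the input.
#'
#' @param data a [labeled_dataset()] with at least 3 rows per class.
#' @param fractions positive train/validation/test fractions summing to 1.
#' @param seed integer seed.
#' @return a `split_bundle`: list with `train`, `valid`, `test` datasets and
#'   the row `indices` of each part.
#' @export
stratified_split <- function(data, fractions = c(0.70, 0.15, 0.15),
                             seed = 1L) {
  stopifnot(inherits(data, "labeled_dataset"), length(fractions) == 3,
            all(fractions > 0), abs(sum(fractions) - 1) < 1e-9)
  if (any(table(data$labels) < 3)) stop("every class needs at least 3 rows")
  idx <- list(train = integer(0), valid = integer(0), test = integer(0))
  with_seed(derive_seed(seed, "split"), {
    for (cls in sort(unique(data$labels))) {
      rows <- sample(which(data$labels == cls))
      n <- length(rows)
      base <- floor(fractions * n)
      left <- n - sum(base)
      # leftover rows go train-first, then validation
      if (left > 0) base[seq_len(left)] <- base[seq_len(left)] + 1L
      cut1 <- base[1]; cut2 <- base[1] + base[2]
      idx$train <- c(idx$train, rows[seq_len(cut1)])
      if (base[2] > 0) idx$valid <- c(idx$valid, rows[(cut1 + 1):cut2])
      if (base[3] > 0) idx$test <- c(idx$test, rows[(cut2 + 1):n])
    }
  })
  idx <- lapply(idx, sort)
  structure(list(train = dataset_rows(data, idx$train),
                 valid = dataset_rows(data, idx$valid),
                 test = dataset_rows(data, idx$test),
                 indices = idx),
            class = "split_bundle")
}

#' Numeric design matrix of a labeled dataset
#'
#' Numeric and time-series columns pass through; categorical columns are
#' encoded per the schema (one-hot for nominal, integer ranks for ordinal).
#'
#' @param data a [labeled_dataset()].
#' @return numeric matrix with one row per sample.
#' @export
design_matrix <- function(data) {
  blocks <- list()
  for (i in seq_len(nrow(data$schema))) {
    nm <- data$schema$name[i]; kind <- data$schema$kind[i]
    if (kind %in% c("numeric", "timeseries")) {
      blocks[[nm]] <- matrix(data$features[[nm]], ncol = 1,
                             dimnames = list(NULL, nm))
    } else {
      enc <- encode_categorical(data$features[[nm]],
                                if (kind == "nominal") "nominal" else "ordinal",
                                data$schema$levels[[i]])
      colnames(enc) <- paste(nm, seq_len(ncol(enc)), sep = "_")
      blocks[[nm]] <- enc
    }
  }
  do.call(cbind, blocks)
}

# Sequence array [n, T, C] for the attention learner: time-series channels if
# present, else each feature becomes a scalar token.
sequence_array <- function(X, schema = NULL) {
  X <- as.matrix(X)
  array(X, dim = c(nrow(X), ncol(X), 1L))
}
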