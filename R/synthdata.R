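#' Specification for a synthetic mixed-type dataset
#'
#' Defines the generating model used throughout the package's tests and
#' examples: a binary class label drawn from `class_prior`, numeric features
#' that are class-conditionally Gaussian with means separated by
#' `mean_separation` (in units of the common within-class standard deviation,
#' which is 1), class-conditionally multinomial categorical features, and
#' AR(1) time-series channels around a class-dependent level. The generator
#' stands in for external clinical datasets so every downstream stage is
#' testable with known ground truth.
#'
#' @param n_samples number of rows.
#' @param n_numeric,n_categorical,n_timeseries feature-family counts; at least
#'   one family must be nonempty.
#' @param class_prior probability of class 1, in (0, 1).
#' @param mean_separation difference between class-conditional numeric means
#'   per feature, in within-class standard deviations (sd = 1).
#' @param categorical_skew in `[0, 1)`: 0 gives identical categorical
#'   distributions in both classes; larger values concentrate mass on a
#'   class-specific level.
#' @param ts_length time steps per series channel.
#' @param ar_coefficient AR(1) coefficient, in (-1, 1).
#' @param missing_rate,outlier_rate corruption rates applied by
#'   [corrupt_dataset()]; stored here for pipeline use.
#' @param seed integer seed governing all draws.
#' @return an object of class `synth_spec`.
#' @seealso [synth_tabular()], [synth_timeseries()], [bayes_accuracy()]
#' @export
synth_spec <- function(n_samples = 1000L, n_numeric = 4L, n_categorical = 0L,
                       n_timeseries = 0L, class_prior = 0.5,
                       mean_separation = 1, categorical_skew = 0.3,
                       ts_length = 10L, ar_coefficient = 0.5,
                       missing_rate = 0, outlier_rate = 0, seed = 1L) {
  stopifnot(is_count(n_samples), n_samples >= 1,
            is_count(n_numeric), is_count(n_categorical), is_count(n_timeseries),
            is.numeric(class_prior), class_prior > 0, class_prior < 1,
            is.numeric(mean_separation), mean_separation >= 0,
            is.numeric(categorical_skew), categorical_skew >= 0, categorical_skew < 1,
            is_count(ts_length), ts_length >= 1,
            is.numeric(ar_coefficient), abs(ar_coefficient) < 1,
            is_prob(missing_rate), is_prob(outlier_rate))
  if (n_numeric + n_categorical + n_timeseries == 0L)
    stop("at least one feature family must be nonempty")
  structure(list(n_samples = as.integer(n_samples),
                 n_numeric = as.integer(n_numeric),
                 n_categorical = as.integer(n_categorical),
                 n_timeseries = as.integer(n_timeseries),
                 class_prior = class_prior, mean_separation = mean_separation,
                 categorical_skew = categorical_skew,
                 ts_length = as.integer(ts_length),
                 ar_coefficient = ar_coefficient,
                 missing_rate = missing_rate, outlier_rate = outlier_rate,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

#' Feature schema for a labeled dataset
#'
#' @param name character vector of unique column names.
#' @param kind one of `"numeric"`, `"nominal"`, `"ordinal"`, `"timeseries"`
#'   per column.
#' @param levels list of level vectors (ordered for ordinal columns), or NULL
#'   entries for numeric/timeseries columns.
#' @return a `feature_schema` data.frame.
#' @export
feature_schema <- function(name, kind, levels = NULL) {
  stopifnot(!anyDuplicated(name), length(name) == length(kind),
            all(kind %in% c("numeric", "nominal", "ordinal", "timeseries")))
  if (is.null(levels)) levels <- vector("list", length(name))
  out <- data.frame(name = name, kind = kind, stringsAsFactors = FALSE)
  out$levels <- levels
  class(out) <- c("feature_schema", "data.frame")
  out
}

#' Construct a labeled dataset
#'
#' A labeled dataset couples a feature table with a binary label vector and a
#' [feature_schema()] declaring every column's kind.
#'
#' @param features data.frame of feature columns.
#' @param labels integer vector of 0/1 class labels, one per row.
#' @param schema a `feature_schema` covering every feature column.
#' @return an object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(features, labels, schema) {
  stopifnot(is.data.frame(features), nrow(features) == length(labels),
            all(labels %in% c(0L, 1L)),
            all(names(features) %in% schema$name),
            all(schema$name %in% names(features)))
  structure(list(features = features, labels = as.integer(labels),
                 schema = schema),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d rows, %d features (%s), class-1 fraction %.3f\n",
              nrow(x$features), ncol(x$features),
              paste(sprintf("%d %s", table(x$schema$kind),
                            names(table(x$schema$kind))), collapse = ", "),
              mean(x$labels)))
  invisible(x)
}

#' @export
dim.labeled_dataset <- function(x) dim(x$features)

# Subset rows of a labeled dataset, keeping schema.
dataset_rows <- function(data, idx) {
  labeled_dataset(data$features[idx, , drop = FALSE], data$labels[idx],
                  data$schema)
}

#' Generate a class-conditional tabular dataset
#'
#' Labels are Bernoulli(`class_prior`). Numeric feature j is N(-d/2, 1) in
#' class 0 and N(+d/2, 1) in class 1 with d = `mean_separation`. Categorical
#' features have 3 levels; class k mixes a uniform distribution with a point
#' mass on level k+1 in proportion `categorical_skew`.
#'
#' @param spec a [synth_spec()].
#' @return a [labeled_dataset()].
#' @export
synth_tabular <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(derive_seed(spec$seed, "tabular"), {
    n <- spec$n_samples
    y <- as.integer(stats::rbinom(n, 1L, spec$class_prior))
    cols <- list()
    kinds <- character(0)
    lvls <- list()
    if (spec$n_numeric > 0) {
      mu <- ifelse(y == 1L, spec$mean_separation / 2, -spec$mean_separation / 2)
      for (j in seq_len(spec$n_numeric)) {
        cols[[paste0("num", j)]] <- stats::rnorm(n, mean = mu, sd = 1)
        kinds <- c(kinds, "numeric"); lvls <- c(lvls, list(NULL))
      }
    }
    if (spec$n_categorical > 0) {
      lv <- c("a", "b", "c")
      for (j in seq_len(spec$n_categorical)) {
        p0 <- rep(1 / 3, 3); p1 <- p0
        p0[1] <- p0[1] * (1 - spec$categorical_skew) + spec$categorical_skew
        p0[2:3] <- p0[2:3] * (1 - spec$categorical_skew)
        p1[2] <- p1[2] * (1 - spec$categorical_skew) + spec$categorical_skew
        p1[c(1, 3)] <- p1[c(1, 3)] * (1 - spec$categorical_skew)
        draw <- function(k, p) sample(lv, k, replace = TRUE, prob = p)
        x <- character(n)
        x[y == 0L] <- draw(sum(y == 0L), p0)
        x[y == 1L] <- draw(sum(y == 1L), p1)
        cols[[paste0("cat", j)]] <- x
        kinds <- c(kinds, "nominal"); lvls <- c(lvls, list(lv))
      }
    }
    features <- as.data.frame(cols, stringsAsFactors = FALSE,
                              optional = TRUE)
    schema <- feature_schema(names(cols), kinds, lvls)
    labeled_dataset(features, y, schema)
  })
}

#' Generate class-conditional AR(1) time-series channels
#'
#' Each channel is a stationary AR(1) process x_t = level + a (x_{t-1} -
#' level) + e_t, e_t ~ N(0, 1), initialized from the stationary distribution;
#' the level is +/- `mean_separation`/2 by class. Series are stored as one
#' column per time step, named `ts<channel>_t<step>`.
#'
#' @param spec a [synth_spec()] with `n_timeseries >= 1` and `ts_length >= 2`.
#' @return a [labeled_dataset()] whose columns all have kind `"timeseries"`.
#' @export
synth_timeseries <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"), spec$n_timeseries >= 1)
  if (spec$ts_length < 2) stop("ts_length must be >= 2")
  a <- spec$ar_coefficient
  with_seed(derive_seed(spec$seed, "timeseries"), {
    n <- spec$n_samples; T <- spec$ts_length
    y <- as.integer(stats::rbinom(n, 1L, spec$class_prior))
    level <- ifelse(y == 1L, spec$mean_separation / 2, -spec$mean_separation / 2)
    cols <- list()
    for (ch in seq_len(spec$n_timeseries)) {
      x <- matrix(0, n, T)
      x[, 1] <- level + stats::rnorm(n, sd = 1 / sqrt(1 - a^2))
      for (t in seq_len(T - 1) + 1L)
        x[, t] <- level + a * (x[, t - 1] - level) + stats::rnorm(n)
      for (t in seq_len(T)) cols[[sprintf("ts%d_t%d", ch, t)]] <- x[, t]
    }
    features <- as.data.frame(cols, optional = TRUE)
    schema <- feature_schema(names(cols), rep("timeseries", length(cols)))
    labeled_dataset(features, y, schema)
  })
}

#' Corrupt a dataset with MCAR missingness and gross outliers
#'
#' Cells are masked missing-completely-at-random at `missing_rate`
#' (independently of values and labels). Outlier cells in numeric and
#' time-series columns are replaced by values at least 8 within-class standard
#' deviations from the feature mean, so both the |Z| > 3 rule and the IQR rule
#' provably flag them. Labels and schema are never altered.
#'
#' @param data a [labeled_dataset()].
#' @param missing_rate,outlier_rate cell-level probabilities.
#' @param seed integer seed.
#' @return a corrupted [labeled_dataset()].
#' @export
corrupt_dataset <- function(data, missing_rate = 0.05, outlier_rate = 0.01,
                            seed = 1L) {
  stopifnot(inherits(data, "labeled_dataset"),
            is_prob(missing_rate), is_prob(outlier_rate))
  if (missing_rate == 0 && outlier_rate == 0) return(data)
  feats <- data$features
  with_seed(derive_seed(seed, "corrupt"), {
    for (nm in names(feats)) {
      kind <- data$schema$kind[data$schema$name == nm]
      n <- nrow(feats)
      if (outlier_rate > 0 && kind %in% c("numeric", "timeseries")) {
        hit <- stats::runif(n) < outlier_rate
        if (any(hit)) {
          mu <- mean(feats[[nm]], na.rm = TRUE)
          sdv <- stats::sd(feats[[nm]], na.rm = TRUE)
          if (!is.finite(sdv) || sdv == 0) sdv <- 1
          shift <- (8 + stats::rexp(sum(hit))) * sdv *
            sample(c(-1, 1), sum(hit), replace = TRUE)
          feats[[nm]][hit] <- mu + shift
        }
      }
      if (missing_rate > 0) {
        miss <- stats::runif(n) < missing_rate
        feats[[nm]][miss] <- NA
      }
    }
  })
  labeled_dataset(feats, data$labels, data$schema)
}

#' Generate a ground-truth / prediction binary mask pair
#'
#' The ground truth is a filled axis-aligned rectangle covering the central
#' half of the grid; the "prediction" flips each pixel independently with
#' probability `flip_prob`. Used as fixtures for the segmentation metrics.
#'
#' @param height,width positive grid dimensions.
#' @param flip_prob per-pixel flip probability.
#' @param seed integer seed.
#' @return list with binary matrices `truth` and `pred`.
#' @export
synth_mask_pair <- function(height, width, flip_prob = 0.1, seed = 1L) {
  stopifnot(is_count(height), height >= 1, is_count(width), width >= 1,
            is_prob(flip_prob))
  truth <- matrix(0L, height, width)
  r <- seq.int(max(1L, floor(height / 4) + 1L), ceiling(3 * height / 4))
  c <- seq.int(max(1L, floor(width / 4) + 1L), ceiling(3 * width / 4))
  truth[r, c] <- 1L
  pred <- with_seed(derive_seed(seed, "mask"), {
    flips <- matrix(stats::runif(height * width) < flip_prob, height, width)
    ifelse(flips, 1L - truth, truth)
  })
  list(truth = truth, pred = matrix(as.integer(pred), height, width))
}

#' Bayes accuracy of the synthetic generating model
#'
#' For a numeric-only, equal-prior, equal-covariance specification with d
#' independent features at per-feature separation delta and unit standard
#' deviation, the optimal rule thresholds the feature sum and attains accuracy
#' Phi(sqrt(d) * delta / 2). Serves as the ceiling in parameter-recovery
#' tests: no classifier can beat it on data drawn from the model.
#'
#' @param spec a [synth_spec()] with only numeric features and prior 0.5.
#' @return the Bayes accuracy, a probability.
#' @export
bayes_accuracy <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  if (spec$n_categorical > 0 || spec$n_timeseries > 0)
    stop("closed-form Bayes accuracy requires a numeric-only spec")
  if (abs(spec$class_prior - 0.5) > 1e-12)
    stop("closed-form Bayes accuracy requires equal class priors")
  stats::pnorm(sqrt(spec$n_numeric) * spec$mean_separation / 2)
}
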