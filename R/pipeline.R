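run_config_defaults <- function() list(
  # synthesis
  n_samples = 1000L, n_numeric = 4L, n_categorical = 0L, n_timeseries = 0L,
  class_prior = 0.5, mean_separation = 1, categorical_skew = 0.3,
  ts_length = 10L, ar_coefficient = 0.5, missing_rate = 0, outlier_rate = 0,
  # preprocessing
  impute_k = 5L, outlier_method = "zscore", z_threshold = 3,
  remove_outliers = TRUE, scale_method = "standard",
  split_train = 0.70, split_valid = 0.15, split_test = 0.15,
  # training (tuning regime: lr 0.001, 0.1 decay / 10 epochs, dropout 0.5,
  # patience 5, batch 64 tabular / 32 image)
  lr = 0.001, lr_decay = 0.1, decay_every = 10L, batch_size = 64L,
  image_batch_size = 32L, epochs = 30L, pretrain_epochs = 10L,
  lr_pretrain = 0.05, cd_k = 1L, lambda = 1e-4, dropout = 0.5,
  patience = 5L, optimizer = "sgd",
  # architecture
  hdbn_layers = c(16L, 8L), dense_hidden = c(32L, 16L), d_model = 16L,
  perf_threshold = 0, max_iter = 10L,
  # misc
  seed = 1L, verbose = FALSE)

#' Load a run configuration
#'
#' Reads a flat YAML key-value file, overlays it on the package defaults,
#' and rejects unknown or wrongly typed keys. An empty (or absent) file
#' yields the pure defaults.
#'
#' @param path YAML file path, or NULL for defaults.
#' @return a `run_config` list.
#' @export
load_run_config <- function(path = NULL) {
  cfg <- run_config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown) > 0)
      stop(sprintf("unknown config key%s: %s",
                   if (length(unknown) > 1) "s" else "",
                   paste(unknown, collapse = ", ")))
    bad <- names(user)[vapply(names(user), function(k)
      !is.null(user[[k]]) && (is.numeric(cfg[[k]]) != is.numeric(user[[k]]) ||
                                is.character(cfg[[k]]) != is.character(user[[k]])),
      logical(1))]
    if (length(bad) > 0)
      stop(sprintf("config key%s with wrong type: %s",
                   if (length(bad) > 1) "s" else "",
                   paste(bad, collapse = ", ")))
    cfg[names(user)] <- user
  }
  structure(cfg, class = "run_config")
}

pipeline_log <- function(cfg, stage, ...) {
  if (isTRUE(cfg$verbose))
    message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full pipeline
#'
#' Orchestrates every stage end to end: synthesize a mixed-type dataset,
#' corrupt it at the configured rates, draw the stratified split, fit
#' imputation and scaling on the training rows only and apply them frozen to
#' all parts, remove flagged training outliers, fit the adaptive ensemble,
#' predict the test split, and compute the full classification report.
#'
#' @param config a [load_run_config()] result (or NULL for defaults).
#' @param out_dir optional directory; when given, the resolved config, the
#'   ensemble weights/history and the metrics report are written as JSON and
#'   the test predictions as CSV.
#' @return list with the fitted `model`, the `report`
#'   ([classification_report()]), the confusion matrix, split sizes and the
#'   resolved config.
#' @export
run_pipeline <- function(config = NULL, out_dir = NULL) {
  cfg <- if (is.null(config)) load_run_config() else config
  stopifnot(inherits(cfg, "run_config"))
  spec <- synth_spec(n_samples = cfg$n_samples, n_numeric = cfg$n_numeric,
                     n_categorical = cfg$n_categorical,
                     n_timeseries = cfg$n_timeseries,
                     class_prior = cfg$class_prior,
                     mean_separation = cfg$mean_separation,
                     categorical_skew = cfg$categorical_skew,
                     ts_length = cfg$ts_length,
                     ar_coefficient = cfg$ar_coefficient, seed = cfg$seed)
  data <- synth_tabular(spec)
  pipeline_log(cfg, "simulate", "n=%d features=%d seed=%d",
               nrow(data$features), ncol(data$features), cfg$seed)
  if (cfg$missing_rate > 0 || cfg$outlier_rate > 0) {
    data <- corrupt_dataset(data, cfg$missing_rate, cfg$outlier_rate,
                            seed = cfg$seed)
    pipeline_log(cfg, "corrupt", "missing=%.3f outliers=%.3f",
                 cfg$missing_rate, cfg$outlier_rate)
  }
  split <- stratified_split(data, c(cfg$split_train, cfg$split_valid,
                                    cfg$split_test), seed = cfg$seed)
  # fit imputation on train only, apply frozen to all parts
  train <- impute_missing(split$train, k = cfg$impute_k)
  imp <- attr(train, "impute_params")
  valid <- impute_missing(split$valid, k = cfg$impute_k, params = imp)
  test <- impute_missing(split$test, k = cfg$impute_k, params = imp)
  num_cols <- train$schema$name[train$schema$kind %in%
                                  c("numeric", "timeseries")]
  if (isTRUE(cfg$remove_outliers) && length(num_cols) > 0) {
    flags <- rep(FALSE, nrow(train$features))
    for (nm in num_cols) {
      x <- train$features[[nm]]
      f <- tryCatch(flag_outliers(x, cfg$outlier_method, cfg$z_threshold),
                    error = function(e) rep(FALSE, length(x)))
      flags <- flags | f
    }
    if (any(flags)) train <- dataset_rows(train, which(!flags))
    pipeline_log(cfg, "outliers", "removed %d training rows", sum(flags))
  }
  Xtr <- design_matrix(train); Xva <- design_matrix(valid)
  Xte <- design_matrix(test)
  scalers <- lapply(seq_len(ncol(Xtr)), function(j) fit_scaler(Xtr[, j]))
  apply_scale <- function(M) {
    out <- vapply(seq_len(ncol(M)), function(j) {
      s <- scalers[[j]]
      if ((cfg$scale_method == "minmax" && s$max == s$min) ||
          (cfg$scale_method == "standard" && s$sd == 0)) M[, j]
      else scale_values(M[, j], cfg$scale_method, s)
    }, numeric(nrow(M)))
    matrix(out, nrow = nrow(M))
  }
  Xtr <- apply_scale(Xtr); Xva <- apply_scale(Xva); Xte <- apply_scale(Xte)
  pipeline_log(cfg, "preprocess", "train=%d valid=%d test=%d width=%d",
               nrow(Xtr), nrow(Xva), nrow(Xte), ncol(Xtr))
  tc <- train_control(lr = cfg$lr, lr_decay = cfg$lr_decay,
                      decay_every = cfg$decay_every,
                      batch_size = cfg$batch_size, epochs = cfg$epochs,
                      pretrain_epochs = cfg$pretrain_epochs,
                      lr_pretrain = cfg$lr_pretrain, cd_k = cfg$cd_k,
                      lambda = cfg$lambda, dropout = cfg$dropout,
                      patience = cfg$patience, optimizer = cfg$optimizer,
                      seed = cfg$seed)
  model <- caen(Xtr, train$labels, Xva, valid$labels, config = tc,
                layer_sizes = cfg$hdbn_layers, hidden = cfg$dense_hidden,
                d_model = cfg$d_model, perf_threshold = cfg$perf_threshold,
                max_iter = cfg$max_iter)
  pipeline_log(cfg, "train", "weights: %s",
               paste(sprintf("%.3f", model$weights), collapse = " "))
  probs <- predict(model, Xte)
  labels <- hard_labels(probs)
  cm <- confusion_matrix(test$labels, labels)
  report <- classification_report(cm)
  pipeline_log(cfg, "evaluate", "test accuracy %.4f", basic_rates(cm)$accuracy)
  result <- list(model = model, report = report, confusion = cm,
                 split_sizes = vapply(split$indices, length, integer(1)),
                 config = cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass(cfg),
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(list(weights = model$weights,
                              losses = model$losses,
                              history = model$history),
                         file.path(out_dir, "ensemble.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(report_json(report, cm),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(data.frame(id = seq_len(nrow(probs)),
                                p_class0 = probs[, 1], p_class1 = probs[, 2],
                                label = labels),
                     file.path(out_dir, "predictions.csv"),
                     row.names = FALSE)
  }
  result
}

report_json <- function(report, cm) {
  list(counts = unclass(cm)[c("tp", "fp", "fn", "tn")],
       accuracy = report$accuracy, precision = report$precision,
       recall = report$recall, specificity = report$specificity,
       fpr = report$fpr, fnr = report$fnr, fdr = report$fdr,
       mcc = report$mcc)
}

#' Write a labeled dataset as CSV with a JSON schema sidecar
#'
#' Missing cells are written empty; the sidecar records every column's kind
#' and levels plus the label column.
#'
#' @param data a [labeled_dataset()].
#' @param csv_path,schema_path output paths.
#' @export
write_dataset <- function(data, csv_path, schema_path) {
  df <- cbind(data$features, label = data$labels)
  utils::write.csv(df, csv_path, row.names = FALSE, na = "")
  jsonlite::write_json(
    list(columns = lapply(seq_len(nrow(data$schema)), function(i)
      list(name = data$schema$name[i], kind = data$schema$kind[i],
           levels = data$schema$levels[[i]])),
      label = "label"),
    schema_path, auto_unbox = TRUE, null = "null")
  invisible(csv_path)
}

#' Read a labeled dataset written by [write_dataset()]
#'
#' @param csv_path,schema_path paths written by [write_dataset()].
#' @return a [labeled_dataset()].
#' @export
read_dataset <- function(csv_path, schema_path) {
  sc <- jsonlite::read_json(schema_path)
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  schema <- feature_schema(
    vapply(sc$columns, `[[`, character(1), "name"),
    vapply(sc$columns, `[[`, character(1), "kind"),
    lapply(sc$columns, function(cl)
      if (is.null(cl$levels)) NULL else unlist(cl$levels)))
  labels <- df[[sc$label]]
  labeled_dataset(df[schema$name], labels, schema)
}
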