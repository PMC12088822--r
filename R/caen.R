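#' Softmax ensemble weights from learner losses
#'
#' w_m = exp(-L_m) / sum_j exp(-L_j): learners with lower losses receive
#' strictly higher weights, and adding a constant to every loss leaves the
#' weights unchanged. Computed with max subtraction for stability.
#'
#' @param losses finite numeric vector of per-learner losses.
#' @return weights summing to 1.
#' @export
softmax_weights <- function(losses) {
  if (length(losses) == 0) stop("empty loss vector")
  if (any(!is.finite(losses))) stop("losses must be finite")
  e <- exp(-(losses - min(losses)))
  e / sum(e)
}

#' Weighted aggregation of base-learner predictions
#'
#' The ensemble prediction is the convex combination sum_m w_m * Yhat_m of
#' the per-learner probability matrices, so every aggregated row still sums
#' to 1.
#'
#' @param predictions list of `[n, 2]` probability matrices of equal shape.
#' @param weights nonnegative weights summing to 1, one per learner.
#' @return aggregated probability matrix.
#' @export
aggregate_predictions <- function(predictions, weights) {
  stopifnot(length(predictions) == length(weights),
            abs(sum(weights) - 1) < 1e-9, all(weights >= 0))
  dims <- lapply(predictions, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
    stop("prediction shape mismatch")
  out <- Reduce(`+`, Map(function(p, w) w * unclass(p), predictions,
                         as.list(weights)))
  structure(out, class = c("prediction", "matrix", "array"))
}

#' Mean cross-entropy of probability predictions
#'
#' -(1/N) sum_i log p_i(true class), with probabilities clipped at `eps` so
#' a confident wrong prediction contributes the finite -log(eps).
#'
#' @param y binary 0/1 labels.
#' @param prob `[n, 2]` probability matrix.
#' @param eps clipping constant.
#' @return scalar loss.
#' @export
cross_entropy <- function(y, prob, eps = 1e-12) {
  prob <- as.matrix(prob)
  if (length(y) == 0) stop("no samples")
  if (length(y) != nrow(prob)) stop("label/prediction row mismatch")
  p_true <- clip_prob(prob[cbind(seq_along(y), y + 1L)], eps)
  -mean(log(p_true))
}

#' Regularized total loss
#'
#' L_total = L + lambda * sum of squared-L2 penalties, the composite
#' objective minimized during optimization.
#'
#' @param loss data loss L.
#' @param sq_norms squared L2 norms of the penalized parameter blocks.
#' @param lambda regularization coefficient (>= 0).
#' @return the total loss.
#' @export
total_loss <- function(loss, sq_norms, lambda) {
  if (lambda < 0) stop("lambda must be nonnegative")
  loss + lambda * sum(sq_norms)
}

#' Fit the custom adaptive ensemble network
#'
#' Trains the three base learners — a hybrid deep belief network, a dense
#' feed-forward network and a self-attention network — on the training
#' split, scores each on the validation split by cross-entropy, and sets the
#' ensemble weights by the softmax rule w_m = exp(-L_m)/sum exp(-L_j). If
#' the aggregated validation accuracy falls below `perf_threshold`, the
#' learners are trained further and losses and weights recalibrated, up to
#' `max_iter` rounds. The full loss/weight history is recorded.
#'
#' The deep belief network receives min-max scaled features; the attention
#' learner receives the sequence array if `sequences` is given, else scalar
#' feature tokens.
#'
#' @param x numeric feature matrix (training split).
#' @param y binary 0/1 labels.
#' @param xval,yval validation split (required: the ensemble weights are
#'   validation quantities).
#' @param sequences optional `[n, T, C]` array (and `sequences_val`) for the
#'   attention learner.
#' @param sequences_val validation sequences when `sequences` is given.
#' @param config a [train_control()].
#' @param layer_sizes deep-belief-network hidden sizes.
#' @param hidden dense-network hidden sizes.
#' @param d_model attention model dimension.
#' @param perf_threshold validation accuracy below which weights are
#'   recalibrated after further training (default 0: one round).
#' @param max_iter maximum recalibration rounds.
#' @param extra_epochs additional training epochs per recalibration round.
#' @param learner_epochs optional named list overriding `config$epochs` per
#'   learner (`hdbn`, `dense`, `attention`); 0 leaves a learner at its
#'   initialization.
#' @return an object of class `caen` with the fitted learners, final
#'   `weights`, per-learner validation `losses`, and an iteration `history`
#'   (losses, weights, ensemble validation cross-entropy and accuracy).
#' @seealso [predict.caen()], [softmax_weights()], [aggregate_predictions()]
#' @export
caen <- function(x, y, xval, yval, sequences = NULL, sequences_val = NULL,
                 config = train_control(), layer_sizes = c(64L, 32L),
                 hidden = c(32L, 16L), d_model = 16L, perf_threshold = 0,
                 max_iter = 10L, extra_epochs = 5L, learner_epochs = NULL) {
  x <- as.matrix(x); xval <- as.matrix(xval)
  if (length(y) != nrow(x) || length(yval) != nrow(xval))
    stop("label/feature row mismatch")
  if (is.null(sequences) != is.null(sequences_val) && !is.null(sequences))
    stop("sequences_val required when sequences is given")
  ep <- function(nm) {
    if (!is.null(learner_epochs) && !is.null(learner_epochs[[nm]]))
      learner_epochs[[nm]] else config$epochs
  }
  cfg_for <- function(nm, iter_extra = 0L) {
    cfg <- config
    cfg$epochs <- as.integer(ep(nm) + iter_extra)
    cfg
  }
  # frozen min-max scaling (train-fitted) for the Bernoulli-visible DBN
  scalers <- apply(x, 2, fit_scaler, simplify = FALSE)
  to_unit <- function(m) {
    out <- vapply(seq_len(ncol(m)), function(j) {
      s <- scalers[[j]]
      if (s$max == s$min) rep(0.5, nrow(m))
      else pmin(pmax((m[, j] - s$min) / (s$max - s$min), 0), 1)
    }, numeric(nrow(m)))
    matrix(out, nrow = nrow(m))
  }
  xu <- to_unit(x); xvu <- to_unit(xval)
  seq_tr <- if (is.null(sequences)) sequence_array(x) else sequences
  seq_va <- if (is.null(sequences)) sequence_array(xval) else sequences_val
  train_all <- function(iter_extra) list(
    hdbn = if (ep("hdbn") + iter_extra >= 1)
      hdbn(xu, y, xvu, yval, layer_sizes, cfg_for("hdbn", iter_extra))
    else untrained_hdbn(ncol(x), layer_sizes, config),
    dense = if (ep("dense") + iter_extra >= 1)
      dense_net(x, y, xval, yval, hidden, cfg_for("dense", iter_extra))
    else untrained_dense(ncol(x), hidden, config),
    attention = if (ep("attention") + iter_extra >= 1)
      attention_net(seq_tr, y, seq_va, yval, d_model,
                    cfg_for("attention", iter_extra))
    else untrained_attention(dim(seq_tr)[2], dim(seq_tr)[3], d_model, config))
  val_input <- list(hdbn = xvu, dense = xval, attention = seq_va)
  history <- list()
  iter <- 0L
  repeat {
    iter <- iter + 1L
    learners <- train_all((iter - 1L) * extra_epochs)
    preds <- Map(function(m, inp) predict_proba(m, inp), learners, val_input)
    losses <- vapply(preds, function(p) cross_entropy(yval, p), numeric(1))
    weights <- softmax_weights(losses)
    agg <- aggregate_predictions(preds, weights)
    acc <- mean(hard_labels(agg) == yval)
    history[[iter]] <- list(iteration = iter, losses = losses,
                            weights = weights,
                            ensemble_ce = cross_entropy(yval, agg),
                            ensemble_accuracy = acc)
    if (acc >= perf_threshold || iter >= max_iter) break
  }
  structure(list(learners = learners, weights = weights, losses = losses,
                 history = history, scalers = scalers,
                 config = config, n_features = ncol(x),
                 own_sequences = is.null(sequences)),
            class = "caen")
}

# Untrained learner stubs (zero training epochs) used for ablations: random
# initialization, no gradient steps.
untrained_hdbn <- function(p, layer_sizes, config) {
  net <- mlp_init(c(p, layer_sizes, 2L),
                  seed = derive_seed(config$seed, "hdbn-init"))
  structure(list(stack = NULL, net = net, layer_sizes = layer_sizes,
                 history = data.frame(epoch = 0L, train_loss = NA_real_,
                                      val_loss = NA_real_),
                 config = config), class = "hdbn")
}

untrained_dense <- function(p, hidden, config) {
  net <- mlp_init(c(p, hidden, 2L),
                  seed = derive_seed(config$seed, "dense-init"))
  structure(list(net = net, hidden = hidden,
                 history = data.frame(epoch = 0L, train_loss = NA_real_,
                                      val_loss = NA_real_),
                 config = config), class = "dense_net")
}

untrained_attention <- function(T, C, d_model, config) {
  params <- attn_init(T, C, d_model, seed = derive_seed(config$seed,
                                                        "attn-init"))
  structure(list(params = params, d_model = d_model, T = T, C = C,
                 history = data.frame(epoch = 0L, train_loss = NA_real_,
                                      val_loss = NA_real_),
                 config = config), class = "attention_net")
}

#' Predict from a fitted adaptive ensemble
#'
#' Aggregates the base learners' probability predictions with the stored
#' softmax weights; hard labels by argmax with ties to class 0.
#'
#' @param object a fitted [caen()].
#' @param newdata numeric feature matrix.
#' @param sequences optional sequence array for the attention learner (when
#'   the model was fitted with explicit sequences).
#' @param type `"prob"` or `"class"`.
#' @param ... unused.
#' @return probability matrix or integer labels.
#' @export
predict.caen <- function(object, newdata, sequences = NULL,
                         type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  if (ncol(x) != object$n_features) stop("feature width mismatch")
  xu <- vapply(seq_len(ncol(x)), function(j) {
    s <- object$scalers[[j]]
    if (s$max == s$min) rep(0.5, nrow(x))
    else pmin(pmax((x[, j] - s$min) / (s$max - s$min), 0), 1)
  }, numeric(nrow(x)))
  xu <- matrix(xu, nrow = nrow(x))
  seqs <- if (object$own_sequences) sequence_array(x) else sequences
  if (is.null(seqs)) stop("sequences required for this model")
  preds <- list(predict_proba(object$learners$hdbn, xu),
                predict_proba(object$learners$dense, x),
                predict_proba(object$learners$attention, seqs))
  agg <- aggregate_predictions(preds, object$weights)
  if (type == "prob") agg else hard_labels(agg)
}

#' @export
print.caen <- function(x, ...) {
  cat("Custom adaptive ensemble network (3 base learners)\n")
  cat(sprintf("  weights: hdbn %.3f, dense %.3f, attention %.3f\n",
              x$weights[1], x$weights[2], x$weights[3]))
  cat(sprintf("  validation cross-entropy: %s\n",
              paste(sprintf("%.4f", x$losses), collapse = ", ")))
  cat(sprintf("  recalibration iterations: %d\n", length(x$history)))
  invisible(x)
}

#' @export
summary.caen <- function(object, ...) {
  hist <- do.call(rbind, lapply(object$history, function(h)
    data.frame(iteration = h$iteration,
               t(stats::setNames(h$losses, paste0("loss_",
                                                  names(h$losses)))),
               t(stats::setNames(h$weights, paste0("w_",
                                                   names(h$weights)))),
               ensemble_ce = h$ensemble_ce,
               ensemble_accuracy = h$ensemble_accuracy)))
  structure(list(history = hist, weights = object$weights,
                 losses = object$losses), class = "summary.caen")
}

#' @export
print.summary.caen <- function(x, ...) {
  cat("Adaptive ensemble fit history\n")
  print(x$history, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.caen <- function(object, ...) object$weights

#' Plot the ensemble weight trajectory
#'
#' Base-R matplot of per-learner weights across recalibration iterations.
#'
#' @param x a fitted [caen()].
#' @param ... passed to [graphics::matplot()].
#' @export
plot.caen <- function(x, ...) {
  W <- do.call(rbind, lapply(x$history, `[[`, "weights"))
  graphics::matplot(seq_len(nrow(W)), W, type = "b", pch = 19,
                    xlab = "recalibration iteration",
                    ylab = "ensemble weight", ylim = c(0, 1), ...)
  graphics::legend("topright", legend = colnames(W) %||%
                     c("hdbn", "dense", "attention"),
                   col = seq_len(ncol(W)), lty = seq_len(ncol(W)), pch = 19)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
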