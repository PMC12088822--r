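#' Fit a hybrid deep belief network
#'
#' Phase-1 model: a stack of Bernoulli RBMs is pretrained greedily by
#' contrastive divergence on inputs scaled to `[0, 1]`, then unrolled into a
#' feed-forward network with logistic activations initialized from the RBM
#' weights and hidden biases, topped with a 2-class softmax head, and
#' fine-tuned end to end by mini-batch gradient descent on cross-entropy plus
#' an L2 weight penalty, with dropout on the head input and early stopping on
#' validation loss.
#'
#' @param x numeric matrix with entries in `[0, 1]` (min-max scale upstream).
#' @param y binary 0/1 labels.
#' @param xval,yval optional validation data; when absent a stratified 15%
#'   of the training rows is held out internally.
#' @param layer_sizes hidden-layer sizes of the RBM stack.
#' @param config a [train_control()].
#' @param pretrain set FALSE to skip layerwise pretraining (random
#'   initialization; used in ablation tests).
#' @return an object of class `hdbn` with elements `stack` (pretrained RBMs),
#'   `net` (fine-tuned weights), `history`, `layer_sizes`.
#' @seealso [extract_features()], [predict.hdbn()]
#' @export
hdbn <- function(x, y, xval = NULL, yval = NULL, layer_sizes = c(64L, 32L),
                 config = train_control(), pretrain = TRUE) {
  x <- as.matrix(x)
  if (length(y) != nrow(x)) stop("label/feature row mismatch")
  if (!all(y %in% c(0, 1))) stop("labels must be binary 0/1")
  if (is.null(xval)) {
    hold <- holdout_rows(y, 0.15, derive_seed(config$seed, "hdbn-holdout"))
    xval <- x[hold, , drop = FALSE]; yval <- y[hold]
    x <- x[-hold, , drop = FALSE]; y <- y[-hold]
  }
  stack <- if (pretrain) pretrain_stack(x, layer_sizes, config) else NULL
  sizes <- c(ncol(x), layer_sizes, 2L)
  net <- mlp_init(sizes, seed = derive_seed(config$seed, "hdbn-init"))
  if (pretrain) {
    for (l in seq_along(stack)) {
      net$W[[l]] <- stack[[l]]$W
      net$b[[l]] <- stack[[l]]$c
    }
  }
  Y <- one_hot(y); Yv <- one_hot(yval)
  nh <- length(layer_sizes)
  fit <- with_seed(derive_seed(config$seed, "hdbn-finetune"), {
    gd_train(net, nrow(x), config,
      loss_grad = function(p, rows, masks)
        mlp_loss_grad(p, x[rows, , drop = FALSE], Y[rows, , drop = FALSE],
                      "sigmoid", config$lambda, masks),
      val_loss = function(p)
        mlp_loss_grad(p, xval, Yv, "sigmoid", config$lambda)$loss,
      make_masks = function(nb) {
        # inverted dropout on the head input (top hidden layer) only
        if (config$dropout <= 0) return(NULL)
        m <- vector("list", nh)
        m[[nh]] <- matrix(stats::rbinom(nb * layer_sizes[nh], 1,
                                        1 - config$dropout) /
                            (1 - config$dropout), nb, layer_sizes[nh])
        m
      })
  })
  structure(list(stack = stack, net = fit$params, history = fit$history,
                 layer_sizes = layer_sizes, config = config),
            class = "hdbn")
}

holdout_rows <- function(y, frac, seed) {
  with_seed(seed, {
    unlist(lapply(unique(y), function(cls) {
      rows <- which(y == cls)
      sample(rows, max(1L, floor(length(rows) * frac)))
    }))
  })
}

#' Extract hierarchical features from a fitted deep belief network
#'
#' Returns the top hidden layer's logistic activations (the representation
#' below the supervised head), one row per sample.
#'
#' @param model a fitted [hdbn()].
#' @param x input matrix with the training dimensionality.
#' @return matrix of activations in (0, 1), width = top layer size.
#' @export
extract_features <- function(model, x) {
  stopifnot(inherits(model, "hdbn"))
  x <- as.matrix(x)
  if (ncol(x) != nrow(model$net$W[[1]])) stop("feature width mismatch")
  a <- x
  for (l in seq_along(model$layer_sizes))
    a <- sigmoid(sweep(a %*% model$net$W[[l]], 2, model$net$b[[l]], `+`))
  a
}

#' Predict class probabilities from a deep belief network
#'
#' @param object a fitted [hdbn()].
#' @param newdata input matrix.
#' @param type `"prob"` for the probability matrix, `"class"` for hard 0/1
#'   labels (argmax, ties to class 0).
#' @param ... unused.
#' @return probability matrix `[n, 2]` or integer labels.
#' @export
predict.hdbn <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  if (ncol(x) != nrow(object$net$W[[1]])) stop("feature width mismatch")
  probs <- mlp_forward(object$net, x, "sigmoid")$probs
  if (type == "prob") probs else hard_labels(probs)
}

# Argmax labels with ties resolved to class 0.
hard_labels <- function(probs) as.integer(probs[, 2] > probs[, 1])

#' @export
print.hdbn <- function(x, ...) {
  cat(sprintf("Hybrid deep belief network: %d -> %s -> 2 (softmax head)\n",
              nrow(x$net$W[[1]]), paste(x$layer_sizes, collapse = " -> ")))
  cat(sprintf("  pretrained: %s; fine-tuned %d epochs (best %d)\n",
              if (is.null(x$stack)) "no" else "yes", max(x$history$epoch),
              x$history$epoch[which.min(x$history$val_loss)]))
  invisible(x)
}
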