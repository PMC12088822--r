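#' Fit a dense feed-forward classifier
#'
#' Multilayer perceptron with rectifier hidden layers, dropout on every
#' hidden layer, and a 2-class softmax head, trained on cross-entropy plus an
#' L2 weight penalty by mini-batch gradient descent with learning-rate decay
#' and early stopping on validation loss.
#'
#' @param x numeric matrix.
#' @param y binary 0/1 labels.
#' @param xval,yval optional validation data (internal stratified 15%
#'   hold-out when absent).
#' @param hidden hidden-layer sizes.
#' @param config a [train_control()].
#' @return an object of class `dense_net`.
#' @export
dense_net <- function(x, y, xval = NULL, yval = NULL, hidden = c(32L, 16L),
                      config = train_control()) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("non-finite inputs")
  if (length(y) != nrow(x)) stop("label/feature row mismatch")
  if (is.null(xval)) {
    hold <- holdout_rows(y, 0.15, derive_seed(config$seed, "dense-holdout"))
    xval <- x[hold, , drop = FALSE]; yval <- y[hold]
    x <- x[-hold, , drop = FALSE]; y <- y[-hold]
  }
  sizes <- c(ncol(x), hidden, 2L)
  net <- mlp_init(sizes, seed = derive_seed(config$seed, "dense-init"))
  Y <- one_hot(y); Yv <- one_hot(yval)
  fit <- with_seed(derive_seed(config$seed, "dense-train"), {
    gd_train(net, nrow(x), config,
      loss_grad = function(p, rows, masks)
        mlp_loss_grad(p, x[rows, , drop = FALSE], Y[rows, , drop = FALSE],
                      "relu", config$lambda, masks),
      val_loss = function(p)
        mlp_loss_grad(p, xval, Yv, "relu", config$lambda)$loss,
      make_masks = function(nb) {
        if (config$dropout <= 0) return(NULL)
        lapply(hidden, function(h)
          matrix(stats::rbinom(nb * h, 1, 1 - config$dropout) /
                   (1 - config$dropout), nb, h))
      })
  })
  structure(list(net = fit$params, hidden = hidden, history = fit$history,
                 config = config),
            class = "dense_net")
}

#' @export
predict.dense_net <- function(object, newdata, type = c("prob", "class"),
                              ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  if (ncol(x) != nrow(object$net$W[[1]])) stop("feature width mismatch")
  probs <- mlp_forward(object$net, x, "relu")$probs
  if (type == "prob") probs else hard_labels(probs)
}

#' @export
print.dense_net <- function(x, ...) {
  cat(sprintf("Dense network: %d -> %s -> 2 (relu, softmax head), %d epochs\n",
              nrow(x$net$W[[1]]), paste(x$hidden, collapse = " -> "),
              max(x$history$epoch)))
  invisible(x)
}

# ---- single-head self-attention classifier ---------------------------------

attn_init <- function(T, C, d, seed = NULL) {
  build <- function() list(
    We = matrix(stats::rnorm(C * d, sd = sqrt(1 / max(C, 1))), C, d),
    be = numeric(d),
    Pe = matrix(stats::rnorm(T * d, sd = 0.1), T, d),
    Wq = matrix(stats::rnorm(d * d, sd = sqrt(1 / d)), d, d),
    Wk = matrix(stats::rnorm(d * d, sd = sqrt(1 / d)), d, d),
    Wv = matrix(stats::rnorm(d * d, sd = sqrt(1 / d)), d, d),
    Wh = matrix(stats::rnorm(d * 2, sd = sqrt(1 / d)), d, 2),
    bh = numeric(2))
  if (is.null(seed)) build() else with_seed(seed, build())
}

# Forward pass of the attention classifier. X is [n, T, C]. Returns caches
# needed for backprop. pool_mask: optional inverted-dropout mask on the
# pooled representation.
attn_forward <- function(params, X, pool_mask = NULL) {
  n <- dim(X)[1]; T <- dim(X)[2]; d <- ncol(params$We)
  tok <- function(t) matrix(X[, t, ], nrow = n)
  H <- lapply(seq_len(T), function(t)
    sweep(tok(t) %*% params$We, 2, params$be + params$Pe[t, ], `+`))
  Q <- lapply(H, function(h) h %*% params$Wq)
  K <- lapply(H, function(h) h %*% params$Wk)
  V <- lapply(H, function(h) h %*% params$Wv)
  # scores S[[i]][, j] = <q_i, k_j> / sqrt(d), vectorized over samples
  S <- lapply(seq_len(T), function(i) {
    s <- matrix(0, n, T)
    for (j in seq_len(T)) s[, j] <- rowSums(Q[[i]] * K[[j]])
    s / sqrt(d)
  })
  A <- lapply(S, softmax_rows)
  Z <- lapply(seq_len(T), function(i) {
    z <- matrix(0, n, d)
    for (j in seq_len(T)) z <- z + A[[i]][, j] * V[[j]]
    z
  })
  P <- Reduce(`+`, Z) / T
  Pd <- if (is.null(pool_mask)) P else P * pool_mask
  logits <- sweep(Pd %*% params$Wh, 2, params$bh, `+`)
  probs <- softmax_rows(logits)
  list(H = H, Q = Q, K = K, V = V, A = A, Z = Z, P = P, Pd = Pd,
       probs = probs, n = n, T = T, d = d)
}

# Cross-entropy + L2 loss and analytic gradients for the attention net.
attn_loss_grad <- function(params, X, Y, lambda, pool_mask = NULL) {
  fw <- attn_forward(params, X, pool_mask)
  n <- fw$n; T <- fw$T; d <- fw$d
  wnorm <- sum(params$We^2) + sum(params$Wq^2) + sum(params$Wk^2) +
    sum(params$Wv^2) + sum(params$Wh^2)
  loss <- -mean(rowSums(Y * log(clip_prob(fw$probs)))) + lambda * wnorm
  dlog <- (fw$probs - Y) / n
  g <- list(We = 2 * lambda * params$We, be = numeric(length(params$be)),
            Pe = params$Pe * 0, Wq = 2 * lambda * params$Wq,
            Wk = 2 * lambda * params$Wk, Wv = 2 * lambda * params$Wv,
            Wh = crossprod(fw$Pd, dlog) + 2 * lambda * params$Wh,
            bh = colSums(dlog))
  dP <- dlog %*% t(params$Wh)
  if (!is.null(pool_mask)) dP <- dP * pool_mask
  dZi <- dP / T                              # same for every position i
  dV <- lapply(seq_len(T), function(j) matrix(0, n, d))
  dH <- lapply(seq_len(T), function(t) matrix(0, n, d))
  for (i in seq_len(T)) {
    dA <- matrix(0, n, T)
    for (j in seq_len(T)) {
      dA[, j] <- rowSums(dZi * fw$V[[j]])
      dV[[j]] <- dV[[j]] + fw$A[[i]][, j] * dZi
    }
    # softmax jacobian over the key axis
    dS <- fw$A[[i]] * (dA - rowSums(fw$A[[i]] * dA))
    dQi <- matrix(0, n, d)
    for (j in seq_len(T)) {
      dQi <- dQi + dS[, j] * fw$K[[j]] / sqrt(d)
      dKj <- dS[, j] * fw$Q[[i]] / sqrt(d)
      dH[[j]] <- dH[[j]] + dKj %*% t(params$Wk)
      g$Wk <- g$Wk + crossprod(fw$H[[j]], dKj)
    }
    dH[[i]] <- dH[[i]] + dQi %*% t(params$Wq)
    g$Wq <- g$Wq + crossprod(fw$H[[i]], dQi)
  }
  for (j in seq_len(T)) {
    dH[[j]] <- dH[[j]] + dV[[j]] %*% t(params$Wv)
    g$Wv <- g$Wv + crossprod(fw$H[[j]], dV[[j]])
  }
  for (t in seq_len(T)) {
    tokt <- matrix(X[, t, ], nrow = n)
    g$We <- g$We + crossprod(tokt, dH[[t]])
    g$be <- g$be + colSums(dH[[t]])
    g$Pe[t, ] <- colSums(dH[[t]])
  }
  list(loss = loss, grads = g)
}

#' Fit a single-head self-attention classifier
#'
#' Tokens are linearly embedded with learned positional embeddings, passed
#' through one scaled dot-product self-attention layer (learned query, key
#' and value projections), mean-pooled over positions, and classified by a
#' softmax head. Tabular inputs without time structure are fed as a sequence
#' of scalar feature tokens, so the learner always applies; the positional
#' embeddings then carry feature identity.
#'
#' @param x 3-d array `[n, T, C]` of sequences, or a numeric matrix (each
#'   column becomes a scalar token).
#' @param y binary 0/1 labels.
#' @param xval,yval optional validation data.
#' @param d_model attention model dimension.
#' @param config a [train_control()]; dropout applies to the pooled
#'   representation.
#' @return an object of class `attention_net`.
#' @export
attention_net <- function(x, y, xval = NULL, yval = NULL, d_model = 16L,
                          config = train_control()) {
  X <- if (is.matrix(x)) sequence_array(x) else x
  if (length(dim(X)) != 3) stop("sequences must form an [n, T, C] array")
  if (length(y) != dim(X)[1]) stop("label/sequence row mismatch")
  if (is.null(xval)) {
    hold <- holdout_rows(y, 0.15, derive_seed(config$seed, "attn-holdout"))
    Xv <- X[hold, , , drop = FALSE]; yval <- y[hold]
    X <- X[-hold, , , drop = FALSE]; y <- y[-hold]
  } else {
    Xv <- if (is.matrix(xval)) sequence_array(xval) else xval
  }
  T <- dim(X)[2]; C <- dim(X)[3]
  params <- attn_init(T, C, d_model, seed = derive_seed(config$seed,
                                                        "attn-init"))
  Y <- one_hot(y); Yv <- one_hot(yval)
  fit <- with_seed(derive_seed(config$seed, "attn-train"), {
    gd_train(params, dim(X)[1], config,
      loss_grad = function(p, rows, masks)
        attn_loss_grad(p, X[rows, , , drop = FALSE],
                       Y[rows, , drop = FALSE], config$lambda, masks),
      val_loss = function(p) attn_loss_grad(p, Xv, Yv, config$lambda)$loss,
      make_masks = function(nb) {
        if (config$dropout <= 0) return(NULL)
        matrix(stats::rbinom(nb * d_model, 1, 1 - config$dropout) /
                 (1 - config$dropout), nb, d_model)
      })
  })
  structure(list(params = fit$params, d_model = d_model, T = T, C = C,
                 history = fit$history, config = config),
            class = "attention_net")
}

#' @export
predict.attention_net <- function(object, newdata, type = c("prob", "class"),
                                  ...) {
  type <- match.arg(type)
  X <- if (is.matrix(newdata)) sequence_array(newdata) else newdata
  if (dim(X)[2] != object$T || dim(X)[3] != object$C)
    stop("sequence shape mismatch")
  probs <- attn_forward(object$params, X)$probs
  if (type == "prob") probs else hard_labels(probs)
}

#' @export
print.attention_net <- function(x, ...) {
  cat(sprintf(paste0("Attention network: %d tokens x %d channels, ",
                     "d_model %d, mean-pooled, softmax head; %d epochs\n"),
              x$T, x$C, x$d_model, max(x$history$epoch)))
  invisible(x)
}

# Attention weights of a fitted model for one batch (diagnostics/tests):
# list over query positions of [n, T] rows summing to 1.
attention_weights <- function(object, newdata) {
  X <- if (is.matrix(newdata)) sequence_array(newdata) else newdata
  attn_forward(object$params, X)$A
}

#' Class-probability predictions under the common learner contract
#'
#' Every base learner (deep belief network, dense network, attention
#' network) returns one `[n, 2]` probability row per input row with rows
#' summing to 1; inference is deterministic (dropout disabled).
#'
#' @param model a fitted `hdbn`, `dense_net` or `attention_net`.
#' @param x input matrix or sequence array.
#' @return probability matrix of class `prediction`.
#' @export
predict_proba <- function(model, x) {
  p <- predict(model, x, type = "prob")
  structure(p, class = c("prediction", class(p)))
}
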