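#' Training configuration
#'
#' Shared hyperparameters for all trainable components. Defaults follow the
#' tuning regime the framework is designed around: initial learning rate
#' 0.001 decayed by a factor of 0.1 every 10 epochs, dropout 0.5, early
#' stopping with patience 5 on validation loss, batch size 64 for tabular
#' data.
#'
#' @param lr initial learning rate for supervised training.
#' @param lr_decay multiplicative decay factor.
#' @param decay_every epochs between decays.
#' @param batch_size mini-batch size.
#' @param epochs maximum supervised epochs.
#' @param pretrain_epochs epochs per RBM during layerwise pretraining.
#' @param lr_pretrain learning rate for contrastive-divergence updates.
#' @param cd_k Gibbs steps per contrastive-divergence update.
#' @param lambda L2 penalty coefficient on weight matrices.
#' @param dropout dropout rate on the supervised head input / hidden layers.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param optimizer `"sgd"` (plain mini-batch gradient descent, the default
#'   update rule) or `"adam"`.
#' @param seed integer seed.
#' @return a `train_control` list.
#' @export
train_control <- function(lr = 0.001, lr_decay = 0.1, decay_every = 10L,
                          batch_size = 64L, epochs = 50L,
                          pretrain_epochs = 15L, lr_pretrain = 0.05,
                          cd_k = 1L, lambda = 1e-4, dropout = 0.5,
                          patience = 5L, optimizer = c("sgd", "adam"),
                          seed = 1L) {
  optimizer <- match.arg(optimizer)
  stopifnot(lr > 0, lambda >= 0, is_count(cd_k), cd_k >= 1,
            is_count(patience), patience >= 1, is_prob(dropout))
  structure(list(lr = lr, lr_decay = lr_decay,
                 decay_every = as.integer(decay_every),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 pretrain_epochs = as.integer(pretrain_epochs),
                 lr_pretrain = lr_pretrain, cd_k = as.integer(cd_k),
                 lambda = lambda, dropout = dropout,
                 patience = as.integer(patience), optimizer = optimizer,
                 seed = as.integer(seed)),
            class = "train_control")
}

#' One gradient-descent step
#'
#' Elementwise update w <- w - lr * grad applied recursively to a (possibly
#' nested) list of parameter arrays.
#'
#' @param params numeric array or list of arrays.
#' @param grads matching gradients.
#' @param lr learning rate.
#' @return updated parameters with the same structure.
#' @export
sgd_step <- function(params, grads, lr) {
  if (is.list(params)) {
    stopifnot(is.list(grads), length(params) == length(grads))
    return(mapply(sgd_step, params, grads, MoreArgs = list(lr = lr),
                  SIMPLIFY = FALSE))
  }
  if (any(!is.finite(grads))) stop("non-finite gradient")
  params - lr * grads
}

# ---- generic multilayer perceptron -----------------------------------------

one_hot <- function(y) {
  Y <- matrix(0, length(y), 2)
  Y[cbind(seq_along(y), y + 1L)] <- 1
  Y
}

mlp_init <- function(sizes, seed = NULL) {
  build <- function() {
    W <- list(); b <- list()
    for (l in seq_len(length(sizes) - 1)) {
      W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1],
                                    sd = sqrt(2 / sizes[l])),
                       sizes[l], sizes[l + 1])
      b[[l]] <- numeric(sizes[l + 1])
    }
    list(W = W, b = b)
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

act_fun <- function(z, activation) {
  switch(activation, relu = pmax(z, 0), sigmoid = sigmoid(z))
}

act_grad <- function(z, a, activation) {
  switch(activation, relu = (z > 0) * 1, sigmoid = a * (1 - a))
}

# Forward pass; dropout_masks is NULL (inference/grad-check) or a list of
# inverted-dropout masks per hidden layer (entries NULL where no dropout).
mlp_forward <- function(params, X, activation, dropout_masks = NULL) {
  L <- length(params$W)
  a <- X
  zs <- vector("list", L); as <- vector("list", L + 1)
  as[[1]] <- a
  for (l in seq_len(L)) {
    z <- sweep(a %*% params$W[[l]], 2, params$b[[l]], `+`)
    zs[[l]] <- z
    if (l < L) {
      a <- act_fun(z, activation)
      if (!is.null(dropout_masks) && !is.null(dropout_masks[[l]]))
        a <- a * dropout_masks[[l]]
    } else {
      a <- softmax_rows(z)
    }
    as[[l + 1]] <- a
  }
  list(zs = zs, as = as, probs = a)
}

# Cross-entropy + L2 loss and analytic gradients for the MLP.
mlp_loss_grad <- function(params, X, Y, activation, lambda,
                          dropout_masks = NULL) {
  n <- nrow(X)
  fw <- mlp_forward(params, X, activation, dropout_masks)
  probs <- clip_prob(fw$probs)
  loss <- -mean(rowSums(Y * log(probs))) +
    lambda * sum(vapply(params$W, function(w) sum(w^2), numeric(1)))
  L <- length(params$W)
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- (fw$probs - Y) / n            # softmax + CE
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(fw$as[[l]], delta) + 2 * lambda * params$W[[l]]
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- delta %*% t(params$W[[l]])
      if (!is.null(dropout_masks) && !is.null(dropout_masks[[l - 1]]))
        delta <- delta * dropout_masks[[l - 1]]
      delta <- delta * act_grad(fw$zs[[l - 1]], act_fun(fw$zs[[l - 1]],
                                                       activation), activation)
    }
  }
  list(loss = loss, grads = list(W = gW, b = gb))
}

scheduled_lr <- function(config, epoch) {
  config$lr * config$lr_decay^(floor((epoch - 1) / config$decay_every))
}

adam_update <- function(params, grads, state, lr, t, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t); vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  flat_p <- unlist_params(params); flat_g <- unlist_params(grads)
  if (is.null(state)) state <- list(m = lapply(flat_p, function(x) x * 0),
                                    v = lapply(flat_p, function(x) x * 0))
  for (i in seq_along(flat_p)) {
    r <- upd(flat_p[[i]], flat_g[[i]], state$m[[i]], state$v[[i]])
    flat_p[[i]] <- r$p; state$m[[i]] <- r$m; state$v[[i]] <- r$v
  }
  list(params = relist_params(flat_p, params), state = state)
}

# Flatten nested parameter lists to a flat list of arrays and back (used by
# the Adam updater and the finite-difference checks).
unlist_params <- function(params) {
  out <- list()
  rec <- function(x, prefix) {
    if (is.list(x)) {
      for (i in seq_along(x)) rec(x[[i]], paste0(prefix, ".", i))
    } else out[[prefix]] <<- x
  }
  rec(params, "p")
  out
}

relist_params <- function(flat, skeleton) {
  i <- 0L
  rec <- function(x) {
    if (is.list(x)) return(lapply(x, rec))
    i <<- i + 1L
    flat[[i]]
  }
  rec(skeleton)
}

# Shared mini-batch training loop with lr decay, dropout, early stopping on
# validation loss. loss_grad(params, rows, masks) must return list(loss,
# grads); val_loss(params) returns the validation objective.
gd_train <- function(params, n, config, loss_grad, val_loss, make_masks) {
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best <- list(params = params, loss = Inf, epoch = 0L)
  wait <- 0L
  adam_state <- NULL; adam_t <- 0L
  for (epoch in seq_len(config$epochs)) {
    lr <- scheduled_lr(config, epoch)
    ord <- sample.int(n)
    starts <- seq(1, n, by = config$batch_size)
    ep_loss <- 0
    for (s in starts) {
      rows <- ord[s:min(s + config$batch_size - 1, n)]
      masks <- make_masks(length(rows))
      lg <- loss_grad(params, rows, masks)
      ep_loss <- ep_loss + lg$loss * length(rows)
      if (config$optimizer == "adam") {
        adam_t <- adam_t + 1L
        au <- adam_update(params, lg$grads, adam_state, lr, adam_t)
        params <- au$params; adam_state <- au$state
      } else {
        params <- sgd_step(params, lg$grads, lr)
      }
    }
    vl <- val_loss(params)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = ep_loss / n,
                                         val_loss = vl))
    if (vl < best$loss - 1e-12) {
      best <- list(params = params, loss = vl, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  list(params = best$params, history = history, best_epoch = best$epoch)
}
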