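#' Construct restricted Boltzmann machine parameters
#'
#' A Bernoulli-Bernoulli RBM over binary visible and hidden units, with
#' bilinear energy E(v, h) = -v' W h - b' v - c' h. Weights are initialized
#' N(0, `init_sd`), biases at zero.
#'
#' @param n_visible,n_hidden layer sizes.
#' @param init_sd standard deviation of the weight initialization.
#' @param seed integer seed (NULL for zero weights).
#' @return an `rbm_params` list with `W` (n_visible x n_hidden), `b`, `c`.
#' @export
rbm_params <- function(n_visible, n_hidden, init_sd = 0.01, seed = NULL) {
  stopifnot(is_count(n_visible), n_visible >= 1, is_count(n_hidden),
            n_hidden >= 1)
  W <- if (is.null(seed)) matrix(0, n_visible, n_hidden) else
    with_seed(seed, matrix(stats::rnorm(n_visible * n_hidden, sd = init_sd),
                           n_visible, n_hidden))
  structure(list(W = W, b = numeric(n_visible), c = numeric(n_hidden)),
            class = "rbm_params")
}

check_rbm_state <- function(v, h, params) {
  if (length(v) != nrow(params$W) || length(h) != ncol(params$W))
    stop("dimension mismatch between state and RBM parameters")
}

#' RBM energy of a joint configuration
#'
#' E(v, h; theta) = - sum_ij v_i W_ij h_j - sum_i b_i v_i - sum_j c_j h_j.
#'
#' @param v,h binary visible and hidden vectors.
#' @param params an [rbm_params()].
#' @return the scalar energy.
#' @export
rbm_energy <- function(v, h, params) {
  check_rbm_state(v, h, params)
  -as.numeric(t(v) %*% params$W %*% h) - sum(params$b * v) - sum(params$c * h)
}

#' Factorial conditional distributions of an RBM
#'
#' The bilinear energy makes both conditionals products of logistic units:
#' p(h_j = 1 | v) = sigmoid(c_j + sum_i v_i W_ij) and symmetrically for the
#' visibles.
#'
#' @param state binary vector: the conditioning layer (visible units for
#'   `"hidden_given_visible"`, hidden units otherwise).
#' @param params an [rbm_params()].
#' @param direction which conditional to evaluate.
#' @return vector of unit activation probabilities.
#' @export
rbm_conditionals <- function(state, params,
                             direction = c("hidden_given_visible",
                                           "visible_given_hidden")) {
  direction <- match.arg(direction)
  if (direction == "hidden_given_visible") {
    if (length(state) != nrow(params$W)) stop("dimension mismatch")
    sigmoid(params$c + as.numeric(state %*% params$W))
  } else {
    if (length(state) != ncol(params$W)) stop("dimension mismatch")
    sigmoid(params$b + as.numeric(params$W %*% state))
  }
}

all_states <- function(n) {
  m <- as.matrix(expand.grid(rep(list(0:1), n)))
  dimnames(m) <- NULL
  m
}

#' Exact partition function by enumeration
#'
#' Sums exp(-E) over all 2^(n_visible + n_hidden) joint states. Only feasible
#' for tiny models; used as the normalization oracle in tests.
#'
#' @param params an [rbm_params()] with at most 20 total units.
#' @return the partition function Z.
#' @export
rbm_partition <- function(params) {
  nv <- nrow(params$W); nh <- ncol(params$W)
  if (nv + nh > 20) stop("model too large for exact enumeration (> 20 units)")
  V <- all_states(nv); H <- all_states(nh)
  # log-sum over all joint states: E(v,h) = -(vWh + bv + ch)
  M <- V %*% params$W %*% t(H) + as.numeric(V %*% params$b) +
    rep(as.numeric(H %*% params$c), each = nrow(V))
  sum(exp(M))
}

#' Exact joint probability of an RBM configuration
#'
#' exp(-E(v, h)) / Z with Z from [rbm_partition()].
#'
#' @inheritParams rbm_energy
#' @return probability of the configuration.
#' @export
rbm_joint_probability <- function(v, h, params) {
  exp(-rbm_energy(v, h, params)) / rbm_partition(params)
}

# Exact model expectations <v h'>, <v>, <h> by enumeration (testing oracle
# and exact-gradient training on tiny models).
rbm_exact_moments <- function(params) {
  nv <- nrow(params$W); nh <- ncol(params$W)
  if (nv + nh > 20) stop("model too large for exact enumeration (> 20 units)")
  V <- all_states(nv); H <- all_states(nh)
  M <- exp(V %*% params$W %*% t(H) + as.numeric(V %*% params$b) +
             rep(as.numeric(H %*% params$c), each = nrow(V)))
  Z <- sum(M)
  P <- M / Z
  list(vh = t(V) %*% P %*% H,
       v = as.numeric(t(V) %*% rowSums(P)),
       h = as.numeric(t(H) %*% colSums(P)))
}

#' Exact average log-likelihood of visible data
#'
#' log P(v) = log sum_h exp(-E(v, h)) - log Z, averaged over the rows of `V`.
#' Enumeration-based; the oracle that contrastive-divergence training is
#' checked against.
#'
#' @param params an [rbm_params()] small enough to enumerate.
#' @param V binary matrix of visible configurations (rows).
#' @return mean log-likelihood.
#' @export
rbm_loglik <- function(params, V) {
  V <- as.matrix(V)
  nh <- ncol(params$W)
  H <- all_states(nh)
  M <- V %*% params$W %*% t(H) + as.numeric(V %*% params$b) +
    rep(as.numeric(H %*% params$c), each = nrow(V))
  mean(log(rowSums(exp(M)))) - log(rbm_partition(params))
}

# Exact log-likelihood gradient: <vh>_data - <vh>_model etc. Positive phase
# uses p(h|v); used for the monotone exact-ascent regression test.
rbm_exact_grad <- function(params, V) {
  V <- as.matrix(V)
  PH <- sigmoid(sweep(V %*% params$W, 2, params$c, `+`))
  mom <- rbm_exact_moments(params)
  list(W = crossprod(V, PH) / nrow(V) - mom$vh,
       b = colMeans(V) - mom$v,
       c = colMeans(PH) - mom$h)
}

# k-step Gibbs chain statistics from starting visibles v0 (rows). The chain
# samples binary states; the final hidden factor uses probabilities (standard
# variance reduction). Returns the negative-phase statistics.
rbm_gibbs_stats <- function(params, v0, k, seed = NULL) {
  run <- function() {
    v <- as.matrix(v0)
    n <- nrow(v)
    for (step in seq_len(k)) {
      ph <- sigmoid(sweep(v %*% params$W, 2, params$c, `+`))
      h <- matrix(stats::rbinom(length(ph), 1L, ph), n)
      pv <- sigmoid(sweep(tcrossprod(h, params$W), 2, params$b, `+`))
      v <- matrix(stats::rbinom(length(pv), 1L, pv), n)
    }
    ph_end <- sigmoid(sweep(v %*% params$W, 2, params$c, `+`))
    list(vh = crossprod(v, ph_end) / n, v = colMeans(v),
         h = colMeans(ph_end), v_samples = v, h_probs = ph_end)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' One contrastive-divergence parameter update
#'
#' CD-k: positive statistics pair the data with p(h | v_data); negative
#' statistics come from a k-step Gibbs chain started at the data (binary
#' samples along the chain, probabilities for the final hidden factor). The
#' update is Delta W = eta (<v h>_data - <v h>_model), with the analogous
#' bias updates.
#'
#' @param params an [rbm_params()].
#' @param batch binary matrix of visible rows.
#' @param k Gibbs steps (>= 1).
#' @param lr learning rate eta.
#' @param seed integer seed for the chain (NULL continues the caller's RNG).
#' @return updated `rbm_params`.
#' @export
cd_update <- function(params, batch, k = 1L, lr = 0.1, seed = NULL) {
  batch <- as.matrix(batch)
  if (nrow(batch) == 0) stop("empty batch")
  stopifnot(is_count(k), k >= 1)
  n <- nrow(batch)
  ph_data <- sigmoid(sweep(batch %*% params$W, 2, params$c, `+`))
  pos <- crossprod(batch, ph_data) / n
  neg <- rbm_gibbs_stats(params, batch, k, seed)
  params$W <- params$W + lr * (pos - neg$vh)
  params$b <- params$b + lr * (colMeans(batch) - neg$v)
  params$c <- params$c + lr * (colMeans(ph_data) - neg$h)
  params
}

#' Greedy layerwise pretraining of an RBM stack
#'
#' Trains the first RBM on the data (values in `[0, 1]` treated as activation
#' probabilities), then each subsequent RBM on the mean-field hidden
#' activations of the frozen layer below.
#'
#' @param X matrix with entries in `[0, 1]`.
#' @param layer_sizes hidden-layer sizes, one per RBM.
#' @param config a [train_control()]; uses `pretrain_epochs`, `batch_size`,
#'   `lr`, `cd_k`, `seed`.
#' @return list of trained [rbm_params()].
#' @export
pretrain_stack <- function(X, layer_sizes, config = train_control()) {
  X <- as.matrix(X)
  if (any(X < -1e-9 | X > 1 + 1e-9)) stop("X must be scaled to [0, 1]")
  if (any(layer_sizes <= 0)) stop("layer sizes must be positive")
  stack <- vector("list", length(layer_sizes))
  input <- X
  with_seed(derive_seed(config$seed, "pretrain"), {
    for (l in seq_along(layer_sizes)) {
      rbm <- rbm_params(ncol(input), layer_sizes[l], seed = NULL)
      rbm$W <- matrix(stats::rnorm(ncol(input) * layer_sizes[l], sd = 0.01),
                      ncol(input), layer_sizes[l])
      n <- nrow(input)
      for (epoch in seq_len(config$pretrain_epochs)) {
        ord <- sample.int(n)
        starts <- seq(1, n, by = config$batch_size)
        for (s in starts) {
          rows <- ord[s:min(s + config$batch_size - 1, n)]
          rbm <- cd_update(rbm, input[rows, , drop = FALSE], k = config$cd_k,
                           lr = config$lr_pretrain)
        }
      }
      stack[[l]] <- rbm
      # mean-field propagation to the next layer
      input <- sigmoid(sweep(input %*% rbm$W, 2, rbm$c, `+`))
    }
  })
  stack
}

# Mean reconstruction error of an RBM on data (diagnostic used in tests).
rbm_reconstruction_error <- function(params, X) {
  ph <- sigmoid(sweep(X %*% params$W, 2, params$c, `+`))
  pv <- sigmoid(sweep(tcrossprod(ph, params$W), 2, params$b, `+`))
  mean((X - pv)^2)
}
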