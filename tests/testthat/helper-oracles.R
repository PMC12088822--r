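# Finite-difference gradient check: maximum relative error between analytic
# and central-difference gradients over every parameter entry.
max_rel_grad_error <- function(params, loss_grad_fn, h = 1e-6) {
  lg <- loss_grad_fn(params)
  flat <- hdbncaen:::unlist_params(params)
  gflat <- hdbncaen:::unlist_params(lg$grads)
  worst <- 0
  for (i in seq_along(flat)) {
    for (j in seq_along(flat[[i]])) {
      fp <- flat; fp[[i]][j] <- fp[[i]][j] + h
      fm <- flat; fm[[i]][j] <- fm[[i]][j] - h
      lp <- loss_grad_fn(hdbncaen:::relist_params(fp, params))$loss
      lm <- loss_grad_fn(hdbncaen:::relist_params(fm, params))$loss
      num <- (lp - lm) / (2 * h)
      an <- gflat[[i]][j]
      # relative criterion, with an absolute floor for near-zero entries
      # where the O(eps/h) difference noise dominates any true gradient
      if (abs(num - an) > 1e-8)
        worst <- max(worst, abs(num - an) / max(1e-8, abs(num) + abs(an)))
    }
  }
  worst
}

# Random enumerable RBM for oracle tests.
random_small_rbm <- function(n_visible, n_hidden, seed, scale = 1) {
  p <- rbm_params(n_visible, n_hidden)
  set.seed(seed)
  p$W <- matrix(rnorm(n_visible * n_hidden, sd = scale), n_visible, n_hidden)
  p$b <- rnorm(n_visible, sd = scale)
  p$c <- rnorm(n_hidden, sd = scale)
  p
}

# Sequences whose class raises the level of the final time segment: the kind
# of temporal signal the attention learner is meant to pick up.
make_segment_sequences <- function(n, T = 8L, shift = 1.5, seed = 1L) {
  set.seed(seed)
  y <- rbinom(n, 1L, 0.5)
  X <- array(rnorm(n * T), c(n, T, 1L))
  seg <- (T %/% 2 + 1L):T
  X[, seg, 1] <- X[, seg, 1] + shift * y
  list(X = X, y = y)
}
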