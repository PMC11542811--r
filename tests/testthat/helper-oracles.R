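# Shared fixtures and independent oracles. Oracles deliberately avoid the
# package code paths they are used to check.

# small, quickly learnable synthetic task (easy: criterion in < 1 epoch)
easy_ds <- function(seed = 11) {
  make_synthetic(synthetic_spec(n_classes = 5, n_features = 60,
                                n_train = 1500, n_valid = 400,
                                noise_sd = 2.0, seed = seed))
}

# harder task where learning time varies with network size
hard_ds <- function(seed = 11) {
  make_synthetic(synthetic_spec(n_classes = 8, n_features = 80,
                                n_train = 3000, n_valid = 600,
                                noise_sd = 2.8, seed = seed))
}

# a tiny random network for unit-level checks
tiny_net <- function(n_in = 4, n_hidden = 3, n_out = 2, seed = 42, sd = 0.5,
                     ...) {
  set.seed(seed)
  w <- mlp_weights(n_in, n_hidden, n_out, init_sd = sd, ...)
  w
}

# finite-difference gradient of the half-SSE loss w.r.t. every weight entry
# (central differences; independent of backprop_proposal)
fd_loss_gradient <- function(weights, x, target, h = 1e-6) {
  loss <- function(w) {
    tr <- forward(w, x)
    0.5 * sum((tr$y - target)^2)
  }
  grad_of <- function(slot) {
    g <- weights[[slot]]
    for (i in seq_along(g)) {
      wp <- weights; wp[[slot]][i] <- wp[[slot]][i] + h
      wm <- weights; wm[[slot]][i] <- wm[[slot]][i] - h
      g[i] <- (loss(wp) - loss(wm)) / (2 * h)
    }
    g
  }
  list(W_in = grad_of("W_in"), W_out = grad_of("W_out"))
}

# dense grid search for the constrained mask optimum (resolution in f1);
# the closed form under test never enters here
grid_search_mask <- function(problem, res = 1e-3) {
  f1_min <- problem$mu / problem$n_hidden # f0 <= 1 constraint
  f1s <- seq(ceiling(f1_min / res) * res, 1, by = res)
  f0s <- problem$mu / (problem$n_hidden * f1s)
  m <- problem$n_in * problem$n_hidden * f0s +
    problem$n_out * problem$n_hidden * f1s
  i <- which.min(m)
  list(f0 = f0s[i], f1 = f1s[i], m = m[i])
}

# reference training loop built only from the public per-sample operations;
# mirrors the RNG consumption of train_to_criterion exactly
manual_train <- function(train, valid, n_hidden, config, strategy,
                         alphas = numeric(0)) {
  n_in <- ncol(train$features); n_out <- ncol(train$targets)
  set.seed(config$seed)
  weights <- mlp_weights(n_in, n_hidden, n_out, init_sd = config$init_sd,
                         beta = config$beta)
  state <- init_strategy(strategy, n_in, n_hidden, n_out)
  ledger <- energy_ledger(alphas = alphas)
  seen <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(nrow(train$features))
    for (s in ord) {
      x <- train$features[s, ]; target <- train$targets[s, ]
      tr <- forward(weights, x)
      prop <- backprop_proposal(weights, tr, x, target, config$learning_rate)
      restricted <- restrict_proposal(state, prop, sample_label = train$labels[s])
      res <- apply_update(weights, restricted)
      weights <- res$weights
      ledger <- charge_update(ledger, restricted$dW_in, "W_in")
      ledger <- charge_update(ledger, restricted$dW_out, "W_out")
      seen <- seen + 1L
      if (seen %% config$eval_every == 0L &&
          evaluate_accuracy(weights, valid) >= config$criterion_accuracy) {
        return(list(T = seen, weights = weights, ledger = ledger))
      }
    }
  }
  list(T = seen, weights = weights, ledger = ledger)
}
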