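#' Train a network to the validation accuracy criterion
#'
#' The central experiment: per-sample SGD with a plasticity restriction
#' strategy and full metabolic bookkeeping. Each sample presentation runs
#' forward pass -> backprop proposal -> strategy restriction -> application
#' (directly, or through the synaptic cache) -> energy charging. Every
#' `config$eval_every` presentations the validation accuracy is measured and
#' training stops at the first evaluation reaching
#' `config$criterion_accuracy`. The iteration count `T` is the number of
#' sample presentations at that point.
#'
#' For the structurally sparse strategies (`full`, `subnet`,
#' `fixed_neuron_mask`, without caching and with the default selection
#' metric) the loop uses an algebraically identical fast path that exploits
#' the rank-1 form of the input-layer update and never materialises the
#' frozen rows; its equivalence to the generic operation chain
#' ([backprop_proposal()] -> [restrict_proposal()] -> [apply_update()] ->
#' [charge_update()]) is covered by the test suite.
#'
#' @param train,valid [labeled_image_set()]s (training and validation).
#' @param n_hidden hidden layer size.
#' @param config a [training_config()].
#' @param strategy a [strategy_spec()].
#' @param caching `NULL` for direct updates, or a list with `theta` and
#'   optionally `lambda_decay`, `c_cost` to train through a synaptic cache
#'   (see [cache_state()]).
#' @param alphas extra energy exponents to track (see [energy_ledger()]).
#' @param potentiation_only charge only positive weight changes.
#' @param track_update_counts record the per-synapse count of non-zero
#'   applied updates (needed for [update_probability_q()]; not supported
#'   together with caching).
#' @return object of class `train_record`: `T` (presentations used),
#'   `converged`, `diverged`, `ledger`, `accuracy_trace` (data frame of
#'   ledger snapshots per evaluation), final `weights` (effective weights
#'   under caching), `update_counts`, plus the `config` and initialised
#'   `strategy` state (fixed masks / subnet index sets are kept for
#'   reproducibility) and the final `cache`.
#' @export
train_to_criterion <- function(train, valid, n_hidden,
                               config = training_config(),
                               strategy = strategy_spec("full"),
                               caching = NULL, alphas = numeric(0),
                               potentiation_only = FALSE,
                               track_update_counts = FALSE) {
  stopifnot(inherits(train, "labeled_image_set"),
            inherits(valid, "labeled_image_set"),
            inherits(config, "training_config"),
            inherits(strategy, "strategy_spec"))
  if (track_update_counts && !is.null(caching)) {
    stop("update-count tracking is not supported with caching", call. = FALSE)
  }
  n_in <- ncol(train$features)
  n_out <- ncol(train$targets)
  n_train <- nrow(train$features)
  lr <- config$learning_rate

  set.seed(config$seed)
  weights <- mlp_weights(n_in, n_hidden, n_out, init_sd = config$init_sd,
                         beta = config$beta,
                         activation_variant = config$activation_variant,
                         output_variant = config$output_variant)
  state <- init_strategy(strategy, n_in, n_hidden, n_out)
  ledger <- energy_ledger(alphas = alphas, potentiation_only = potentiation_only)
  cache <- if (!is.null(caching)) {
    cache_state(weights,
                theta = caching$theta,
                lambda_decay = caching$lambda_decay %||% 1e-3,
                c_cost = caching$c_cost %||% 0.01)
  }
  counts <- if (track_update_counts) {
    list(W_in = matrix(0L, n_hidden, n_in + 1L),
         W_out = matrix(0L, n_out, n_hidden + 1L))
  }

  fast <- is.null(caching) && strategy$selection_metric == "update_magnitude" &&
    strategy$variant %in% c("full", "subnet", "fixed_neuron_mask")
  plastic <- state$plastic_units %||% seq_len(n_hidden)

  samples_seen <- 0L
  converged <- FALSE
  diverged <- FALSE
  trace <- list()

  eval_weights <- function() if (is.null(cache)) weights else effective_weights(cache, weights)

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n_train)
    for (s in ord) {
      x <- train$features[s, ]
      target <- train$targets[s, ]
      w_eff <- eval_weights()
      tr <- forward(w_eff, x)
      if (!all(is.finite(tr$y))) { diverged <- TRUE; break }
      if (fast) {
        # restricted rows only; float-for-float the same operations as the
        # generic backprop_proposal -> restrict_proposal -> apply_update path
        err <- backprop_errors(w_eff, tr, target)
        xa <- c(x, 1)
        ya <- c(tr$a_hidden, 1)
        if (strategy$variant == "subnet") {
          ya[setdiff(seq_len(n_hidden), plastic)] <- 0
        }
        dpart_in <- -lr * tcrossprod(err$delta_hidden[plastic], xa)
        dW_out <- -lr * tcrossprod(err$delta_out, ya)
        if (!all(is.finite(dpart_in)) || !all(is.finite(dW_out))) {
          diverged <- TRUE; break
        }
        weights$W_in[plastic, ] <- weights$W_in[plastic, , drop = FALSE] + dpart_in
        weights$W_out <- weights$W_out + dW_out
        ledger <- charge_update(ledger, dpart_in, "W_in")
        ledger <- charge_update(ledger, dW_out, "W_out")
        if (track_update_counts) {
          counts$W_in[plastic, ] <- counts$W_in[plastic, , drop = FALSE] +
            (dpart_in != 0)
          counts$W_out <- counts$W_out + (dW_out != 0)
        }
      } else {
        err <- backprop_errors(w_eff, tr, target)
        proposal <- backprop_proposal(w_eff, tr, x, target, lr)
        restricted <- restrict_proposal(state, proposal,
                                        sample_label = train$labels[s],
                                        hidden_errors = err$delta_hidden,
                                        hidden_activities = tr$a_hidden)
        if (!all(is.finite(restricted$dW_in)) ||
            !all(is.finite(restricted$dW_out))) {
          diverged <- TRUE; break
        }
        if (is.null(cache)) {
          res <- apply_update(weights, restricted)
          weights <- res$weights
          ledger <- charge_update(ledger, restricted$dW_in, "W_in")
          ledger <- charge_update(ledger, restricted$dW_out, "W_out")
          if (track_update_counts) {
            counts$W_in <- counts$W_in + (restricted$dW_in != 0)
            counts$W_out <- counts$W_out + (restricted$dW_out != 0)
          }
        } else {
          stepped <- caching_step(cache, restricted, ledger)
          cache <- stepped$cache
          ledger <- stepped$ledger
        }
      }
      samples_seen <- samples_seen + 1L
      if (samples_seen %% config$eval_every == 0L) {
        acc <- evaluate_accuracy(eval_weights(), valid)
        trace[[length(trace) + 1L]] <- data.frame(
          samples_seen = samples_seen, accuracy = acc,
          m0 = ledger$m0, m1 = ledger$m1,
          transient_cost = ledger$transient_cost)
        if (acc >= config$criterion_accuracy) { converged <- TRUE; break }
      }
    }
    if (converged || diverged) break
  }

  structure(
    list(T = samples_seen, converged = converged, diverged = diverged,
         ledger = ledger,
         accuracy_trace = if (length(trace)) do.call(rbind, trace) else
           data.frame(samples_seen = integer(0), accuracy = numeric(0),
                      m0 = numeric(0), m1 = numeric(0),
                      transient_cost = numeric(0)),
         weights = eval_weights(), update_counts = counts,
         config = config, strategy = state, cache = cache),
    class = "train_record"
  )
}

#' @export
print.train_record <- function(x, ...) {
  acc <- if (nrow(x$accuracy_trace)) utils::tail(x$accuracy_trace$accuracy, 1) else NA
  cat("<train_record> T =", x$T, "presentations,",
      if (x$diverged) "DIVERGED" else if (x$converged) "converged" else
        "criterion not reached",
      "\n  final accuracy:", if (is.na(acc)) "n/a" else sprintf("%.3f", acc),
      " M0:", format(x$ledger$m0, big.mark = ","),
      " M1:", signif(x$ledger$m1, 5),
      if (x$ledger$transient_cost > 0)
        paste(" transient:", signif(x$ledger$transient_cost, 5)), "\n")
  invisible(x)
}

#' One-row run summary
#' @param x a `train_record`.
#' @param ... unused.
#' @export
as.data.frame.train_record <- function(x, ...) {
  cbind(
    data.frame(n_hidden = nrow(x$weights$W_in), strategy = x$strategy$spec$variant,
               T = x$T, converged = x$converged, diverged = x$diverged,
               seed = x$config$seed,
               final_accuracy = if (nrow(x$accuracy_trace))
                 utils::tail(x$accuracy_trace$accuracy, 1) else NA_real_),
    as.data.frame(x$ledger)
  )
}

#' Least-squares power-law fit
#'
#' Fits `y = a * x^b` by ordinary least squares on `(log x, log y)`; exact on
#' noiseless power laws. Used for the energy-vs-size and time-vs-size scaling
#' exponents.
#'
#' @param xs,ys positive numeric vectors (at least two distinct `xs`).
#' @return object of class `power_law_fit` with `exponent` (b), `prefactor`
#'   (a) and `r_squared`.
#' @export
fit_power_law <- function(xs, ys) {
  if (length(xs) != length(ys) || length(xs) < 2L) {
    stop("need at least two (x, y) pairs", call. = FALSE)
  }
  if (any(xs <= 0) || any(ys <= 0)) {
    stop("power-law fit requires strictly positive values", call. = FALSE)
  }
  if (length(unique(xs)) < 2L) {
    stop("all x values identical; exponent is unidentifiable", call. = FALSE)
  }
  fit <- stats::lm(log(ys) ~ log(xs))
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((log(ys) - mean(log(ys)))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(exponent = unname(stats::coef(fit)[2L]),
                 prefactor = exp(unname(stats::coef(fit)[1L])),
                 r_squared = r2),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> y = %.4g * x^%.4f  (r^2 = %.4f)\n",
              x$prefactor, x$exponent, x$r_squared))
  invisible(x)
}

#' Extrapolate the training-cost ratio to a cortex-scale synapse count
#'
#' Given a fitted scaling exponent of energy versus hidden-layer size, asks
#' how much more energy a network with `n_syn_target` synapses (e.g. the
#' ~3e11 synapses of macaque V1) would spend than the minimal
#' criterion-reaching reference network. The target synapse count is
#' converted to an equivalent hidden-layer size through the synapses added
#' per hidden unit (784 + 10 = 794 for the MNIST geometry, biases excluded),
#' and the ratio is `(N_h_equivalent / N_h_ref)^exponent`.
#'
#' @param exponent fitted power-law exponent (0.75 for the update-count
#'   energy, 0.43 for the accumulated-change energy).
#' @param n_syn_target synapse count to extrapolate to (default `3e11`).
#' @param syn_per_hidden synapses per hidden unit (default `794`).
#' @param n_hidden_ref reference hidden-layer size (default 100, the
#'   smallest size that reaches the criterion).
#' @return list with `ratio`, `n_hidden_equivalent`, `nearest_decade`
#'   (`10^round(log10(ratio))`) and `one_sig_fig` (`signif(ratio, 1)`).
#' @export
extrapolate_ratio <- function(exponent, n_syn_target = 3e11,
                              syn_per_hidden = 794, n_hidden_ref = 100) {
  if (n_syn_target <= 0 || syn_per_hidden <= 0 || n_hidden_ref <= 0) {
    stop("sizes must be positive", call. = FALSE)
  }
  n_eq <- n_syn_target / syn_per_hidden
  ratio <- (n_eq / n_hidden_ref)^exponent
  list(ratio = ratio, n_hidden_equivalent = n_eq,
       nearest_decade = 10^round(log10(ratio)),
       one_sig_fig = signif(ratio, 1))
}

#' Inverse Simpson index of the update distribution
#'
#' Measures how evenly non-zero updates were distributed over synapses
#' during a run: with `p_i` the share of updates landing on synapse `i`,
#' `q = 1 / (N * sum p_i^2)` where `N` is the number of synapses considered.
#' `q = 1` when updates are spread uniformly over all synapses and `q = k/N`
#' when always the same `k` synapses are updated -- so `q` well above `k/N`
#' under top-k selection shows the competition keeps switching synapses
#' rather than acting like a fixed mask.
#'
#' @param update_counts numeric vector or matrix (or list of matrices, e.g.
#'   `record$update_counts`) of per-synapse non-zero update counts.
#' @return `q` in `(0, 1]`.
#' @export
update_probability_q <- function(update_counts) {
  if (is.list(update_counts)) {
    update_counts <- unlist(lapply(update_counts, as.vector))
  }
  counts <- as.numeric(update_counts)
  if (any(counts < 0)) stop("negative update counts", call. = FALSE)
  tot <- sum(counts)
  if (tot == 0) stop("all update counts are zero", call. = FALSE)
  p <- counts / tot
  1 / (length(p) * sum(p^2))
}

#' Energy/time sweep over network sizes
#'
#' Runs criterion training for every combination of hidden-layer size and
#' seed and returns one summary row per run. The strategy may depend on the
#' size (e.g. optimal mask fractions per size) via `strategy_fn`.
#'
#' @param sizes integer vector of hidden-layer sizes.
#' @param seeds integer vector of RNG seeds (each reseeds initialisation and
#'   sample order; the dataset is fixed).
#' @param train,valid datasets, as in [train_to_criterion()].
#' @param config a [training_config()]; its `seed` is overridden per run.
#' @param strategy_fn function `n_hidden -> strategy_spec`.
#' @param ... further arguments passed to [train_to_criterion()].
#' @return data frame with one row per `(size, seed)` run.
#' @export
energy_size_sweep <- function(sizes, seeds, train, valid,
                              config = training_config(),
                              strategy_fn = function(n_hidden) strategy_spec("full"),
                              ...) {
  rows <- list()
  for (nh in sizes) {
    for (sd_ in seeds) {
      cfg <- config
      cfg$seed <- as.integer(sd_)
      rec <- train_to_criterion(train, valid, n_hidden = nh, config = cfg,
                                strategy = strategy_fn(nh), ...)
      rows[[length(rows) + 1L]] <- as.data.frame(rec)
    }
  }
  do.call(rbind, rows)
}
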