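#' Plasticity restriction strategy specification
#'
#' Declares which synapses are allowed to change on each sample presentation.
#' Variants:
#' \describe{
#'   \item{`full`}{vanilla backprop; every synapse updates every sample.}
#'   \item{`dropconnect`}{a fresh Bernoulli mask per sample (both layers,
#'     same fraction `f0`); with `per_class = TRUE`, one persistent mask per
#'     class label, drawn on first use.}
#'   \item{`fixed_synapse_mask`}{Bernoulli(`f0`) mask over the input layer
#'     and Bernoulli(`f1`) over the output layer, drawn once and fixed for
#'     the whole run.}
#'   \item{`fixed_neuron_mask`}{a fixed random subset of `subnet_size` hidden
#'     units whose back-propagated error survives; their incoming weights are
#'     the only plastic input-layer synapses, the output layer stays fully
#'     plastic.}
#'   \item{`subnet`}{coordinated plasticity: incoming AND outgoing synapses
#'     of a fixed subset of `subnet_size` hidden units are plastic, so the
#'     plastic synapses form paths through the network (the output bias,
#'     belonging to no hidden unit, stays plastic).}
#'   \item{`topk`}{competitive selection, recomputed every sample: keep only
#'     the `ceiling(topk_fraction * n)` largest-magnitude proposed updates of
#'     the input layer (`topk_scope = "layer"` across the layer, `"neuron"`
#'     within each hidden unit's row); the output layer is always updated in
#'     full. If `subnet_size` is also set, the competition runs inside the
#'     subnet only and output columns outside the subnet are frozen.
#'     `selection_metric` switches to the exploratory per-neuron variants
#'     that keep rows of the hidden units with largest error or activity.}
#' }
#'
#' @param variant one of the strategy names above.
#' @param f0,f1 plastic fractions for input and output layer, in `(0, 1]`.
#' @param subnet_size number of plastic hidden units (neuron mask / subnet /
#'   subnet-restricted top-k).
#' @param topk_fraction fraction of input-layer updates kept under `topk`.
#' @param topk_scope `"layer"` or `"neuron"`.
#' @param per_class dropconnect only: persistent per-class masks.
#' @param selection_metric `"update_magnitude"` (default), `"neuron_error"`,
#'   or `"neuron_activity"`.
#' @param seed optional seed for drawing the fixed structures.
#' @return object of class `strategy_spec`.
#' @export
strategy_spec <- function(variant = c("full", "dropconnect",
                                      "fixed_synapse_mask",
                                      "fixed_neuron_mask", "subnet", "topk"),
                          f0 = 1, f1 = 1, subnet_size = NULL,
                          topk_fraction = 1,
                          topk_scope = c("layer", "neuron"),
                          per_class = FALSE,
                          selection_metric = c("update_magnitude",
                                               "neuron_error",
                                               "neuron_activity"),
                          seed = NULL) {
  variant <- match.arg(variant)
  topk_scope <- match.arg(topk_scope)
  selection_metric <- match.arg(selection_metric)
  stopifnot(f0 > 0, f0 <= 1, f1 > 0, f1 <= 1,
            topk_fraction > 0, topk_fraction <= 1)
  if (variant %in% c("fixed_neuron_mask", "subnet") && is.null(subnet_size)) {
    stop("variant '", variant, "' needs subnet_size", call. = FALSE)
  }
  if (!is.null(subnet_size)) stopifnot(subnet_size >= 1)
  structure(list(variant = variant, f0 = f0, f1 = f1,
                 subnet_size = if (!is.null(subnet_size)) as.integer(subnet_size),
                 topk_fraction = topk_fraction, topk_scope = topk_scope,
                 per_class = isTRUE(per_class),
                 selection_metric = selection_metric,
                 seed = seed),
            class = "strategy_spec")
}

#' Initialise the per-run state of a strategy
#'
#' Draws the fixed structures once: Bernoulli synapse masks for
#' `fixed_synapse_mask`, a uniform random subset of hidden units for
#' `fixed_neuron_mask`, `subnet` and subnet-restricted `topk`. Deterministic
#' given `spec$seed` (falls back to the current RNG stream when unset).
#'
#' @param spec a [strategy_spec()].
#' @param n_in,n_hidden,n_out network dimensions.
#' @return object of class `strategy_state` carrying `spec`, optional
#'   `mask_in`/`mask_out` binary matrices, optional `plastic_units` index
#'   vector, and an environment for lazily-drawn per-class masks.
#' @export
init_strategy <- function(spec, n_in, n_hidden, n_out) {
  stopifnot(inherits(spec, "strategy_spec"))
  if (!is.null(spec$subnet_size) && spec$subnet_size > n_hidden) {
    stop("subnet_size ", spec$subnet_size, " exceeds hidden layer size ",
         n_hidden, call. = FALSE)
  }
  if (!is.null(spec$seed)) set.seed(spec$seed)
  state <- list(spec = spec, mask_in = NULL, mask_out = NULL,
                plastic_units = NULL, class_masks = new.env(parent = emptyenv()),
                dims = c(n_in = n_in, n_hidden = n_hidden, n_out = n_out))
  if (spec$variant == "fixed_synapse_mask") {
    state$mask_in <- matrix(stats::rbinom(n_hidden * (n_in + 1L), 1L, spec$f0),
                            n_hidden, n_in + 1L)
    state$mask_out <- matrix(stats::rbinom(n_out * (n_hidden + 1L), 1L, spec$f1),
                             n_out, n_hidden + 1L)
  }
  if (spec$variant %in% c("fixed_neuron_mask", "subnet") ||
      (spec$variant == "topk" && !is.null(spec$subnet_size))) {
    state$plastic_units <- sort(sample.int(n_hidden, spec$subnet_size))
  }
  structure(state, class = "strategy_state")
}

# keep the k largest values of av (a vector of |delta|), ties broken by
# ascending flat index so the kept count is exact and deterministic
topk_keep <- function(av, k) {
  if (k >= length(av)) return(rep(TRUE, length(av)))
  keep <- logical(length(av))
  ord <- order(-av, seq_along(av))
  keep[ord[seq_len(k)]] <- TRUE
  keep
}

#' Restrict an update proposal to the plastic synapses
#'
#' Transforms the raw backprop proposal into the changes actually applied,
#' according to the strategy in `state`. Fixed-mask and subnet variants are
#' projections (idempotent, constant support); dropconnect draws fresh masks
#' from the current RNG stream; top-k recomputes its competitive selection
#' for every call.
#'
#' @param state a [init_strategy()] state.
#' @param proposal an `update_proposal` from [backprop_proposal()].
#' @param sample_label class label of the current sample (per-class
#'   dropconnect only).
#' @param hidden_errors,hidden_activities per-unit `delta` and activation
#'   vectors (exploratory selection metrics only).
#' @return the restricted `update_proposal`.
#' @export
restrict_proposal <- function(state, proposal, sample_label = NULL,
                              hidden_errors = NULL, hidden_activities = NULL) {
  spec <- state$spec
  dW_in <- proposal$dW_in
  dW_out <- proposal$dW_out
  n_hidden <- nrow(dW_in)
  switch(spec$variant,
    full = {},
    dropconnect = {
      if (spec$per_class) {
        if (is.null(sample_label)) stop("per-class dropconnect needs sample_label", call. = FALSE)
        key <- as.character(sample_label)
        if (is.null(state$class_masks[[key]])) {
          state$class_masks[[key]] <- list(
            m_in = matrix(stats::rbinom(length(dW_in), 1L, spec$f0), nrow(dW_in)),
            m_out = matrix(stats::rbinom(length(dW_out), 1L, spec$f0), nrow(dW_out))
          )
        }
        m <- state$class_masks[[key]]
        dW_in <- dW_in * m$m_in
        dW_out <- dW_out * m$m_out
      } else {
        dW_in <- dW_in * stats::rbinom(length(dW_in), 1L, spec$f0)
        dW_out <- dW_out * stats::rbinom(length(dW_out), 1L, spec$f0)
      }
    },
    fixed_synapse_mask = {
      dW_in <- dW_in * state$mask_in
      dW_out <- dW_out * state$mask_out
    },
    fixed_neuron_mask = {
      frozen <- setdiff(seq_len(n_hidden), state$plastic_units)
      dW_in[frozen, ] <- 0
    },
    subnet = {
      frozen <- setdiff(seq_len(n_hidden), state$plastic_units)
      dW_in[frozen, ] <- 0
      dW_out[, frozen] <- 0 # bias column (n_hidden + 1) stays plastic
    },
    topk = {
      rows <- state$plastic_units %||% seq_len(n_hidden)
      if (!is.null(state$plastic_units)) {
        frozen <- setdiff(seq_len(n_hidden), rows)
        dW_in[frozen, ] <- 0
        dW_out[, frozen] <- 0
      }
      if (spec$selection_metric == "update_magnitude") {
        if (spec$topk_scope == "layer") {
          block <- dW_in[rows, , drop = FALSE]
          k <- ceiling(spec$topk_fraction * length(block))
          block[!topk_keep(abs(as.vector(block)), k)] <- 0
          dW_in[rows, ] <- block
        } else {
          k <- ceiling(spec$topk_fraction * ncol(dW_in))
          for (r in rows) {
            dW_in[r, !topk_keep(abs(dW_in[r, ]), k)] <- 0
          }
        }
      } else {
        metric <- if (spec$selection_metric == "neuron_error") {
          if (is.null(hidden_errors)) stop("neuron_error metric needs hidden_errors", call. = FALSE)
          abs(hidden_errors)
        } else {
          if (is.null(hidden_activities)) stop("neuron_activity metric needs hidden_activities", call. = FALSE)
          abs(hidden_activities)
        }
        k <- ceiling(spec$topk_fraction * length(rows))
        keep_rows <- rows[topk_keep(metric[rows], k)]
        dW_in[setdiff(seq_len(n_hidden), keep_rows), ] <- 0
      }
    }
  )
  proposal$dW_in <- dW_in
  proposal$dW_out <- dW_out
  proposal
}

`%||%` <- function(a, b) if (is.null(a)) b else a
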