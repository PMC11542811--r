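#' Two-compartment synaptic cache state
#'
#' Splits each synaptic weight into a cheap, decaying transient component and
#' a costly persistent component; the effective connection strength is always
#' `w_pers + w_trans`. Updates land in the transient compartment; whenever a
#' transient entry reaches the consolidation threshold `theta` in absolute
#' value, it is added to the persistent weight and reset to zero. Only
#' consolidation events are charged to the update-count energy M0; holding
#' transient weight costs `c * sum |w_trans|` per sample presentation.
#'
#' @param weights an [mlp_weights()] providing the initial persistent
#'   weights (transient components start at zero).
#' @param theta consolidation threshold `>= 0`; `theta = 0` makes every
#'   non-zero update consolidate immediately, reproducing vanilla training
#'   bit for bit.
#' @param lambda_decay per-sample decay rate of the transient weights
#'   (default `1e-3`).
#' @param c_cost transient maintenance cost constant (default 0.01).
#' @return object of class `cache_state` with `w_trans`, `w_pers` (lists
#'   with `W_in`, `W_out` slots) and the three parameters.
#' @export
cache_state <- function(weights, theta, lambda_decay = 1e-3, c_cost = 0.01) {
  stopifnot(inherits(weights, "mlp_weights"),
            theta >= 0, lambda_decay >= 0, lambda_decay <= 1, c_cost >= 0)
  structure(
    list(
      w_trans = list(W_in = weights$W_in * 0, W_out = weights$W_out * 0),
      w_pers = list(W_in = weights$W_in, W_out = weights$W_out),
      theta = theta, lambda_decay = lambda_decay, c_cost = c_cost
    ),
    class = "cache_state"
  )
}

#' Effective weights of a cached network
#'
#' @param cache a [cache_state()].
#' @param weights an `mlp_weights` template (for activation metadata).
#' @return `weights` with `W_in`/`W_out` set to `w_pers + w_trans`.
#' @export
effective_weights <- function(cache, weights) {
  weights$W_in <- cache$w_pers$W_in + cache$w_trans$W_in
  weights$W_out <- cache$w_pers$W_out + cache$w_trans$W_out
  weights
}

#' One sample presentation of cached plasticity
#'
#' Fixed operation order per sample: (1) decay the transient weights by
#' `(1 - lambda)`, (2) add the restricted update deltas to the transient
#' compartment, (3) consolidate every entry whose transient magnitude reaches
#' `theta` (and is non-zero): the transient value moves into the persistent
#' weight, the ledger is charged one M0 event and `|w_trans|` of M1, and the
#' entry resets to zero, (4) charge the transient maintenance cost
#' `c * sum |w_trans|` on the post-consolidation state. The decay-first order
#' is what makes `theta = 0` exactly equivalent to vanilla training.
#'
#' @param cache a [cache_state()].
#' @param restricted_deltas an `update_proposal` after strategy restriction.
#' @param ledger an [energy_ledger()].
#' @return list with updated `cache` and `ledger`.
#' @export
caching_step <- function(cache, restricted_deltas, ledger) {
  for (layer in c("W_in", "W_out")) {
    d <- restricted_deltas[[if (layer == "W_in") "dW_in" else "dW_out"]]
    if (!all(is.finite(d))) stop("non-finite deltas", call. = FALSE)
    wt <- (1 - cache$lambda_decay) * cache$w_trans[[layer]]
    wt <- wt + d
    consolidate <- abs(wt) >= cache$theta & wt != 0
    if (any(consolidate)) {
      moved <- wt[consolidate]
      cache$w_pers[[layer]][consolidate] <-
        cache$w_pers[[layer]][consolidate] + moved
      ledger <- charge_update(ledger, moved, layer)
      wt[consolidate] <- 0
    }
    cache$w_trans[[layer]] <- wt
    ledger <- charge_transient(ledger, wt, cache$c_cost, layer)
  }
  list(cache = cache, ledger = ledger)
}
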