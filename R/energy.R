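#' Metabolic energy ledger for synaptic plasticity
#'
#' Accumulates the M_alpha family of plasticity cost measures over a training
#' run: for applied weight changes `Dw` summed over synapses and time,
#' `M_alpha = sum |Dw|^alpha`. Two members are of primary interest:
#' `M0` counts the number of non-zero updates irrespective of size (tracked
#' as a direct count, not as an `alpha -> 0` limit) and `M1` accumulates the
#' absolute weight change. An exact-zero test decides M0 increments: with
#' zero-meaned inputs, accidental exact zeros do not occur. Under the
#' potentiation-only variant, only positive changes are charged (all
#' accumulators). The ledger also carries the maintenance cost of transient
#' weights under synaptic caching, which by construction contributes to M1
#' accounting but never to M0.
#'
#' @param alphas numeric vector of additional exponents `alpha > 0` to track
#'   (`M1` is always tracked; listing `1` here simply mirrors it).
#' @param potentiation_only logical; charge only `Dw > 0` (cost model variant
#'   in which depression is free).
#' @param layers character names of the per-layer breakdown slots.
#' @return object of class `energy_ledger` with fields `m0`, `m1`, `m_alpha`
#'   (named by exponent), `transient_cost`, `potentiation_only`, `per_layer`.
#' @export
energy_ledger <- function(alphas = numeric(0), potentiation_only = FALSE,
                          layers = c("W_in", "W_out")) {
  stopifnot(all(alphas > 0))
  slot <- function() {
    list(m0 = 0, m1 = 0,
         m_alpha = stats::setNames(numeric(length(alphas)),
                                   as.character(alphas)),
         transient_cost = 0)
  }
  led <- slot()
  led$potentiation_only <- isTRUE(potentiation_only)
  led$per_layer <- stats::setNames(replicate(length(layers), slot(),
                                             simplify = FALSE), layers)
  structure(led, class = "energy_ledger")
}

#' @export
print.energy_ledger <- function(x, ...) {
  cat("<energy_ledger> M0 =", format(x$m0, big.mark = ","),
      " M1 =", signif(x$m1, 6),
      if (x$transient_cost > 0) paste(" transient =", signif(x$transient_cost, 6)),
      if (x$potentiation_only) " (potentiation-only)", "\n")
  for (a in names(x$m_alpha)) {
    cat("  M_", a, " = ", signif(x$m_alpha[[a]], 6), "\n", sep = "")
  }
  invisible(x)
}

charge_slot <- function(slot, deltas, potentiation_only) {
  sel <- if (potentiation_only) deltas > 0 else deltas != 0
  d <- abs(deltas[sel])
  slot$m0 <- slot$m0 + length(d)
  slot$m1 <- slot$m1 + sum(d)
  for (a in names(slot$m_alpha)) {
    slot$m_alpha[[a]] <- slot$m_alpha[[a]] + sum(d^as.numeric(a))
  }
  slot
}

#' Charge applied weight changes to the ledger
#'
#' Adds one batch of applied deltas (one layer, one sample presentation) to
#' all tracked accumulators: `m0 += #\{Dw != 0\}` (exact test),
#' `m1 += sum |Dw|`, and `m_alpha += sum |Dw|^alpha` per tracked exponent;
#' restricted to `Dw > 0` under the potentiation-only variant. The per-layer
#' breakdown is updated alongside the totals.
#'
#' @param ledger an [energy_ledger()].
#' @param applied_deltas numeric matrix/vector of actually-applied changes.
#' @param layer_id name of the layer slot (`"W_in"` or `"W_out"`).
#' @return the updated ledger.
#' @export
charge_update <- function(ledger, applied_deltas, layer_id) {
  if (!all(is.finite(applied_deltas))) {
    stop("non-finite applied deltas", call. = FALSE)
  }
  if (!layer_id %in% names(ledger$per_layer)) {
    stop("unknown layer '", layer_id, "'", call. = FALSE)
  }
  po <- ledger$potentiation_only
  ledger[c("m0", "m1", "m_alpha")] <-
    charge_slot(ledger[c("m0", "m1", "m_alpha")], applied_deltas, po)
  ledger$per_layer[[layer_id]] <-
    charge_slot(ledger$per_layer[[layer_id]], applied_deltas, po)
  ledger
}

#' Charge the maintenance cost of transient weights
#'
#' Under synaptic caching, holding weight in the cheap transient compartment
#' still costs `c * sum |w_trans|` per sample presentation. This adds to
#' `transient_cost` (an M1-like term) and never touches `m0`.
#'
#' @param ledger an [energy_ledger()].
#' @param transient_weights numeric matrix/vector of transient components.
#' @param c_cost maintenance cost constant `c >= 0` (default 0.01).
#' @param layer_id layer slot for the breakdown.
#' @return the updated ledger.
#' @export
charge_transient <- function(ledger, transient_weights, c_cost = 0.01,
                             layer_id = "W_in") {
  stopifnot(c_cost >= 0)
  inc <- c_cost * sum(abs(transient_weights))
  ledger$transient_cost <- ledger$transient_cost + inc
  ledger$per_layer[[layer_id]]$transient_cost <-
    ledger$per_layer[[layer_id]]$transient_cost + inc
  ledger
}

#' Flatten a ledger into a one-row data frame
#'
#' Convenience for run logs: totals plus per-layer columns.
#'
#' @param x an [energy_ledger()].
#' @param ... unused.
#' @export
as.data.frame.energy_ledger <- function(x, ...) {
  out <- data.frame(m0 = x$m0, m1 = x$m1, transient_cost = x$transient_cost)
  for (a in names(x$m_alpha)) out[[paste0("m_alpha_", a)]] <- x$m_alpha[[a]]
  for (l in names(x$per_layer)) {
    out[[paste0(l, "_m0")]] <- x$per_layer[[l]]$m0
    out[[paste0(l, "_m1")]] <- x$per_layer[[l]]$m1
  }
  out
}
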