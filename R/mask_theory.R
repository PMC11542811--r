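#' Mask-optimisation problem
#'
#' The counting argument behind fixed random masks: reaching criterion
#' performance needs about `mu` plastic input->hidden->output paths (about
#' 100 for MNIST-like tasks, the smallest fully-plastic network that reaches
#' the criterion). Bernoulli masks with plastic fractions `f0` (input layer)
#' and `f1` (output layer) leave on average `f0 * f1 * N_h` such paths, while
#' the energy of training is proportional to the number of plastic synapses
#' `m(f0, f1) = n_in N_h f0 + n_out N_h f1`. Minimising `m` subject to the
#' path constraint gives the closed-form optimal fractions.
#'
#' Derivation (documented because the constrained optimum has a boundary):
#' substituting `f0 = mu / (f1 N_h)` into `m` gives
#' `m(f1) = mu n_in / f1 + n_out N_h f1`, which is convex in `f1` with
#' unconstrained minimum `f1 = sqrt(mu n_in / (N_h n_out))`. Clipping at the
#' `f1 <= 1` boundary yields
#' `f1* = min(1, sqrt(mu n_in / (N_h n_out)))`, `f0* = mu / (N_h f1*)`, and
#' `m* = mu n_in max(1, sqrt(N_h n_out / (mu n_in))) +
#'       N_h n_out min(1, sqrt(mu n_in / (N_h n_out)))`.
#' The boundary leaves `f1* = 1` for all `N_h <= mu n_in / n_out` (7840 for
#' the defaults, i.e. about 8000): only beyond that size does it pay to
#' freeze part of the output layer. For very large `N_h` both terms grow as
#' `sqrt(N_h)`.
#'
#' @param mu required number of plastic paths (default 100).
#' @param n_in number of input units (default 784).
#' @param n_out number of output units (default 10).
#' @param n_hidden hidden layer size `N_h` (must be `>= mu` for the
#'   constraint to be satisfiable with fractions `<= 1`).
#' @return object of class `mask_problem`.
#' @export
mask_problem <- function(n_hidden, mu = 100, n_in = 784, n_out = 10) {
  stopifnot(n_hidden >= 1, mu >= 1, n_in >= 1, n_out >= 1)
  if (n_hidden < mu) {
    stop("infeasible: n_hidden = ", n_hidden, " < mu = ", mu,
         " (f0*f1*N_h = mu requires N_h >= mu)", call. = FALSE)
  }
  structure(list(mu = mu, n_in = n_in, n_out = n_out, n_hidden = n_hidden),
            class = "mask_problem")
}

#' Mean number of plastic paths under random masks
#'
#' @param f0,f1 plastic fractions per layer, in `[0, 1]`.
#' @param n_hidden hidden layer size.
#' @return `f0 * f1 * n_hidden`.
#' @export
plastic_paths <- function(f0, f1, n_hidden) {
  check_fraction(f0); check_fraction(f1)
  f0 * f1 * n_hidden
}

#' Energy proxy: number of plastic synapses
#'
#' @param f0,f1 plastic fractions per layer, in `[0, 1]`.
#' @param problem a [mask_problem()].
#' @return `n_in * N_h * f0 + n_out * N_h * f1`.
#' @export
proxy_cost <- function(f0, f1, problem) {
  check_fraction(f0); check_fraction(f1)
  problem$n_in * problem$n_hidden * f0 + problem$n_out * problem$n_hidden * f1
}

check_fraction <- function(f) {
  if (any(!is.finite(f)) || any(f < 0) || any(f > 1)) {
    stop("plastic fractions must lie in [0, 1]", call. = FALSE)
  }
  invisible(f)
}

#' Closed-form optimal mask fractions
#'
#' Minimises [proxy_cost()] subject to `f0 * f1 * N_h = mu`, `0 < f <= 1`
#' (see [mask_problem()] for the derivation).
#'
#' @param problem a [mask_problem()].
#' @return list with `f0`, `f1` (optimal fractions) and `m` (minimal proxy
#'   cost); the constraint `f0 * f1 * N_h = mu` holds exactly.
#' @export
optimal_fractions <- function(problem) {
  stopifnot(inherits(problem, "mask_problem"))
  with(problem, {
    f1 <- min(1, sqrt(mu * n_in / (n_hidden * n_out)))
    f0 <- mu / (n_hidden * f1)
    m <- mu * n_in * max(1, sqrt(n_hidden * n_out / (mu * n_in))) +
      n_hidden * n_out * min(1, sqrt(mu * n_in / (n_hidden * n_out)))
    list(f0 = f0, f1 = f1, m = m)
  })
}

#' Network size above which the output layer should be partially frozen
#'
#' The boundary `N_h` at which the optimal output-layer fraction `f1*` drops
#' below 1, obtained from `sqrt(mu n_in / (N_h n_out)) = 1`:
#' `N_h = mu n_in / n_out`. For the defaults (`mu = 100`, `n_in = 784`,
#' `n_out = 10`) this is 7840, i.e. roughly 8000 hidden units -- below that
#' size all hidden-to-output synapses should stay plastic.
#'
#' @param problem a [mask_problem()] (its `n_hidden` is ignored).
#' @return the boundary hidden-layer size `mu * n_in / n_out`.
#' @export
f1_threshold_size <- function(problem) {
  with(problem, mu * n_in / n_out)
}

#' Theory table over a grid of network sizes
#'
#' Evaluates the closed-form optimum for each size; used for overlaying the
#' analytic curve on empirical energy-vs-size sweeps (the proxy predicts
#' shape only -- its proportionality constant is fitted to one empirical
#' point).
#'
#' @param sizes integer vector of hidden-layer sizes (each `>= mu`).
#' @param mu,n_in,n_out see [mask_problem()].
#' @return data frame with columns `n_hidden`, `f0`, `f1`, `m`,
#'   `plastic_paths`.
#' @export
mask_theory_table <- function(sizes, mu = 100, n_in = 784, n_out = 10) {
  rows <- lapply(sizes, function(nh) {
    pr <- mask_problem(nh, mu = mu, n_in = n_in, n_out = n_out)
    opt <- optimal_fractions(pr)
    data.frame(n_hidden = nh, f0 = opt$f0, f1 = opt$f1, m = opt$m,
               plastic_paths = plastic_paths(opt$f0, opt$f1, nh))
  })
  do.call(rbind, rows)
}
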