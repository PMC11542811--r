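#' Two-layer perceptron weights
#'
#' Builds the weight state of a single-hidden-layer perceptron:
#' `W_in` is `n_hidden x (n_in + 1)` and `W_out` is `n_out x (n_hidden + 1)`,
#' where the last column of each matrix is the bias, treated as a synapse
#' from a constant-1 input. Biases therefore participate in masking and
#' energy accounting like any other synapse. Hidden units use a leaky
#' rectifier `g(x) = x` for `x >= 0` and `g(x) = beta * x` otherwise
#' (`beta = 0.1` by default; `beta = 0` recovers the plain ReLU); output
#' units are linear under the default mean-squared-error convention, or a
#' softmax under the cross-entropy variant.
#'
#' @param n_in,n_hidden,n_out layer sizes.
#' @param init_sd sd of the Gaussian weight initialisation (default 0.01).
#' @param beta leak slope of the hidden activation (default 0.1).
#' @param activation_variant `"lrelu"` or `"relu"` (relu is lrelu with slope 0).
#' @param output_variant `"linear_mse"` (default) or `"softmax_ce"`.
#' @param seed optional integer seed for the initial draw.
#' @return object of class `mlp_weights`.
#' @export
mlp_weights <- function(n_in, n_hidden, n_out, init_sd = 0.01, beta = 0.1,
                        activation_variant = c("lrelu", "relu"),
                        output_variant = c("linear_mse", "softmax_ce"),
                        seed = NULL) {
  activation_variant <- match.arg(activation_variant)
  output_variant <- match.arg(output_variant)
  if (activation_variant == "relu") beta <- 0
  if (!is.null(seed)) set.seed(seed)
  w <- structure(
    list(
      W_in = matrix(stats::rnorm(n_hidden * (n_in + 1L), sd = init_sd),
                    n_hidden, n_in + 1L),
      W_out = matrix(stats::rnorm(n_out * (n_hidden + 1L), sd = init_sd),
                     n_out, n_hidden + 1L),
      beta = beta,
      activation_variant = activation_variant,
      output_variant = output_variant
    ),
    class = "mlp_weights"
  )
  w
}

#' @export
print.mlp_weights <- function(x, ...) {
  cat("<mlp_weights> ", ncol(x$W_in) - 1L, "-", nrow(x$W_in), "-",
      nrow(x$W_out), " (", x$activation_variant, "/", x$output_variant,
      ", beta=", x$beta, ", ", n_synapses(x), " synapses incl. biases)\n",
      sep = "")
  invisible(x)
}

#' Total synapse count of a network, biases included
#' @param weights an `mlp_weights`.
#' @export
n_synapses <- function(weights) {
  length(weights$W_in) + length(weights$W_out)
}

lrelu <- function(h, beta) ifelse(h >= 0, h, beta * h)
lrelu_grad <- function(h, beta) ifelse(h >= 0, 1, beta)

softmax <- function(h) {
  e <- exp(h - max(h))
  e / sum(e)
}

#' Forward pass for a single sample
#'
#' @param weights an [mlp_weights()].
#' @param x numeric feature vector of length `n_in`.
#' @return object of class `forward_trace` with `h_hidden` (net inputs),
#'   `a_hidden` (activations) and `y` (network outputs; raw linear outputs
#'   under `linear_mse`, softmax probabilities under `softmax_ce`).
#' @export
forward <- function(weights, x) {
  n_in <- ncol(weights$W_in) - 1L
  if (length(x) != n_in) {
    stop("input has length ", length(x), ", expected ", n_in, call. = FALSE)
  }
  h <- drop(weights$W_in %*% c(x, 1))
  a <- lrelu(h, weights$beta)
  y <- drop(weights$W_out %*% c(a, 1))
  if (weights$output_variant == "softmax_ce") y <- softmax(y)
  structure(list(h_hidden = h, a_hidden = a, y = y), class = "forward_trace")
}

#' Raw backpropagation update proposal
#'
#' Computes the per-sample weight-change proposal `Delta w = -eps * delta * x`
#' without applying it. Under the default linear-output MSE convention the
#' output error is `delta_out = y - t`; the hidden error is the
#' back-propagated error scaled by the activation derivative. The proposal is
#' what the plasticity strategies then restrict; only the restricted part is
#' ever applied and charged for.
#'
#' @param weights an [mlp_weights()].
#' @param trace the [forward()] trace produced from `(weights, x)`.
#' @param x the input vector used for the trace.
#' @param target one-hot (or general) target vector of length `n_out`.
#' @param learning_rate the learning rate `eps`.
#' @return object of class `update_proposal` with `dW_in`, `dW_out`,
#'   `learning_rate`.
#' @export
backprop_proposal <- function(weights, trace, x, target, learning_rate = 0.01) {
  if (length(trace$a_hidden) != nrow(weights$W_in)) {
    stop("trace is inconsistent with weights", call. = FALSE)
  }
  if (length(target) != nrow(weights$W_out)) {
    stop("target has wrong length", call. = FALSE)
  }
  err <- backprop_errors(weights, trace, target)
  structure(
    list(
      dW_in = -learning_rate * tcrossprod(err$delta_hidden, c(x, 1)),
      dW_out = -learning_rate * tcrossprod(err$delta_out, c(trace$a_hidden, 1)),
      learning_rate = learning_rate
    ),
    class = "update_proposal"
  )
}

# output and hidden error vectors; shared by the public proposal builder and
# the specialised training fast paths
backprop_errors <- function(weights, trace, target) {
  delta_out <- trace$y - target # g' = 1 (linear); softmax+CE gives same form
  n_hidden <- nrow(weights$W_in)
  delta_hidden <- lrelu_grad(trace$h_hidden, weights$beta) *
    drop(crossprod(weights$W_out[, seq_len(n_hidden), drop = FALSE], delta_out))
  list(delta_out = delta_out, delta_hidden = delta_hidden)
}

#' Apply a (restricted) update proposal to the weights
#'
#' Adds the proposal entrywise and returns both the new weights and the
#' actually-applied deltas, which are what the energy ledger is charged with.
#'
#' @param weights an [mlp_weights()].
#' @param proposal an `update_proposal` (usually after restriction).
#' @return list with `weights` (updated) and `applied` (the proposal deltas,
#'   identical to the input by construction).
#' @export
apply_update <- function(weights, proposal) {
  if (!all(dim(proposal$dW_in) == dim(weights$W_in)) ||
      !all(dim(proposal$dW_out) == dim(weights$W_out))) {
    stop("proposal shape does not match weights", call. = FALSE)
  }
  if (!all(is.finite(proposal$dW_in)) || !all(is.finite(proposal$dW_out))) {
    stop("non-finite entries in update proposal", call. = FALSE)
  }
  weights$W_in <- weights$W_in + proposal$dW_in
  weights$W_out <- weights$W_out + proposal$dW_out
  list(weights = weights, applied = proposal)
}

# batched forward pass over the rows of a feature matrix (internal, used for
# evaluation where the per-sample loop would dominate runtime)
forward_batch <- function(weights, features) {
  n <- nrow(features)
  H <- tcrossprod(features, weights$W_in[, -ncol(weights$W_in), drop = FALSE])
  H <- sweep(H, 2L, weights$W_in[, ncol(weights$W_in)], "+")
  A <- lrelu(H, weights$beta)
  Y <- tcrossprod(A, weights$W_out[, -ncol(weights$W_out), drop = FALSE])
  Y <- sweep(Y, 2L, weights$W_out[, ncol(weights$W_out)], "+")
  Y # softmax is monotone per row, argmax unchanged; skip it for evaluation
}

#' Classification accuracy on a dataset
#'
#' Fraction of samples whose argmax network output matches the label, ties
#' broken in favour of the lowest output index.
#'
#' @param weights an [mlp_weights()].
#' @param dataset a [labeled_image_set()].
#' @return fraction in `[0, 1]`.
#' @export
evaluate_accuracy <- function(weights, dataset) {
  stopifnot(inherits(dataset, "labeled_image_set"), nrow(dataset$features) > 0L)
  Y <- forward_batch(weights, dataset$features)
  pred <- max.col(Y, ties.method = "first") - 1L
  mean(pred == dataset$labels)
}

#' Training loop configuration
#'
#' Bundles the hyperparameters of criterion training: per-sample SGD at a
#' fixed learning rate, Gaussian `sd = init_sd` initialisation, samples
#' presented in a fresh uniform shuffle each epoch, validation accuracy
#' measured every `eval_every` sample presentations, and training stopped at
#' the first evaluation reaching `criterion_accuracy`.
#'
#' @param learning_rate fixed SGD learning rate `eps` (default 0.01, the
#'   compromise value at which the update-count and accumulated-change energy
#'   measures can be compared on one run).
#' @param init_sd weight initialisation sd (default 0.01).
#' @param criterion_accuracy validation accuracy stopping criterion
#'   (default 0.95).
#' @param eval_every evaluation interval in sample presentations (default 1000).
#' @param max_epochs epoch cap; a run that never reaches criterion within it
#'   is returned with `converged = FALSE`.
#' @param seed integer seed controlling initialisation and sample order.
#' @param beta,activation_variant,output_variant forwarded to [mlp_weights()].
#' @export
training_config <- function(learning_rate = 0.01, init_sd = 0.01,
                            criterion_accuracy = 0.95, eval_every = 1000L,
                            max_epochs = 20L, seed = 1L, beta = 0.1,
                            activation_variant = "lrelu",
                            output_variant = "linear_mse") {
  stopifnot(learning_rate > 0, init_sd >= 0,
            criterion_accuracy > 0, criterion_accuracy <= 1,
            eval_every >= 1L, max_epochs >= 1L)
  structure(list(learning_rate = learning_rate, init_sd = init_sd,
                 criterion_accuracy = criterion_accuracy,
                 eval_every = as.integer(eval_every),
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed), beta = beta,
                 activation_variant = activation_variant,
                 output_variant = output_variant),
            class = "training_config")
}
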