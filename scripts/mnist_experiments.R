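#!/usr/bin/env Rscript
# Reproduces the MNIST-dependent numbers (not run by the test suite: needs
# the four IDX files downloaded manually, see README).
#
# Usage:
#   Rscript scripts/mnist_experiments.R --data-dir <dir with IDX files> \
#       [--quick] [--out results/mnist]
#
# With --quick only the minimal-run update count is computed (~minutes);
# the full scaled-down sweep (sizes 100/300/1000/3000, 3 seeds) takes hours
# on one CPU.

suppressPackageStartupMessages(library(plastenergy))

args <- commandArgs(trailingOnly = TRUE)
arg_of <- function(flag, default = NULL) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) default else args[i + 1L]
}
data_dir <- arg_of("--data-dir", "data/mnist")
out_dir <- arg_of("--out", "results/mnist")
quick <- "--quick" %in% args
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

message("loading MNIST from ", data_dir)
full <- read_idx(file.path(data_dir, "train-images-idx3-ubyte"),
                 file.path(data_dir, "train-labels-idx1-ubyte"))
# hold out 10,000 training samples for validation; official test set unused
idx_valid <- seq_len(10000L)
valid <- labeled_image_set(full$features[idx_valid, ], full$labels[idx_valid],
                           n_classes = 10L)
train <- labeled_image_set(full$features[-idx_valid, ], full$labels[-idx_valid],
                           n_classes = 10L)
zm <- zero_mean(train, list(valid))
train <- zm$train; valid <- zm$others[[1L]]

## Minimal criterion run (N_h = 100): total update count M0
rec <- train_to_criterion(train, valid, n_hidden = 100,
                          config = training_config(seed = 1, max_epochs = 30))
cat(sprintf("N_h = 100: T = %d, M0 = %.3g (>= 1e8 expected), M1 = %.3g\n",
            rec$T, rec$ledger$m0, rec$ledger$m1))

if (!quick) {
  ## Scaled-down scaling sweep: exponents for T, M0, M1 vs size
  sw <- energy_size_sweep(c(100, 300, 1000, 3000), seeds = 1:3, train, valid,
                          config = training_config(max_epochs = 30))
  utils::write.csv(sw, file.path(out_dir, "size_sweep.csv"), row.names = FALSE)
  agg <- aggregate(cbind(T, m0, m1) ~ n_hidden, sw, mean)
  cat(sprintf("T exponent:  %.3f (paper: -0.249)\n",
              fit_power_law(agg$n_hidden, agg$T)$exponent))
  cat(sprintf("M0 exponent: %.3f (paper: 0.75)\n",
              fit_power_law(agg$n_hidden, agg$m0)$exponent))
  cat(sprintf("M1 exponent: %.3f (paper: 0.43)\n",
              fit_power_law(agg$n_hidden, agg$m1)$exponent))

  ## Update-diversity q on a 1000-unit top-k run
  rq <- train_to_criterion(train, valid, n_hidden = 1000,
                           config = training_config(seed = 1, max_epochs = 30),
                           strategy = strategy_spec("topk", topk_fraction = 0.01,
                                                    topk_scope = "layer"),
                           track_update_counts = TRUE)
  cat(sprintf("top-k q = %.3f (paper: ~0.6, k/N = 0.01)\n",
              update_probability_q(rq$update_counts$W_in)))
}
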