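test_that("the fast training path reproduces the generic operation chain", {
  ds <- easy_ds()
  cfg <- training_config(seed = 21, max_epochs = 1, criterion_accuracy = 1,
                         eval_every = 300)
  for (spec in list(strategy_spec("full"),
                    strategy_spec("subnet", subnet_size = 4),
                    strategy_spec("fixed_neuron_mask", subnet_size = 4))) {
    rec <- train_to_criterion(ds$train, ds$valid, n_hidden = 8, config = cfg,
                              strategy = spec)
    ref <- manual_train(ds$train, ds$valid, n_hidden = 8, config = cfg,
                        strategy = spec)
    expect_identical(rec$T, ref$T)
    expect_identical(rec$weights$W_in, ref$weights$W_in)
    expect_identical(rec$weights$W_out, ref$weights$W_out)
    expect_identical(rec$ledger$m0, ref$ledger$m0)
    expect_identical(rec$ledger$m1, ref$ledger$m1)
  }
})

test_that("power-law fitting recovers exponents", {
  xs <- c(10, 100, 1000)
  fit <- fit_power_law(xs, 2 * xs^0.75)
  expect_equal(fit$exponent, 0.75, tolerance = 1e-12)
  expect_equal(fit$prefactor, 2, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # multiplicative lognormal noise, sd 0.05: exponent within +/- 0.05
  set.seed(99)
  errs <- replicate(100, {
    x <- 10^seq(1, 3, length.out = 20)
    y <- 3 * x^0.6 * exp(rnorm(20, sd = 0.05))
    fit_power_law(x, y)$exponent - 0.6
  })
  expect_lt(max(abs(errs)), 0.05)

  expect_error(fit_power_law(c(10, 10), c(1, 2)), "identical")
  expect_error(fit_power_law(c(-1, 2), c(1, 2)), "positive")
  expect_error(fit_power_law(3, 5), "two")
})

test_that("cortex-scale extrapolation arithmetic", {
  m0 <- extrapolate_ratio(0.75, n_syn_target = 3e11, syn_per_hidden = 794,
                          n_hidden_ref = 100)
  expect_equal(m0$n_hidden_equivalent, 3e11 / 794)
  expect_equal(m0$ratio, (3e11 / 794 / 100)^0.75, tolerance = 1e-12)
  m1 <- extrapolate_ratio(0.43)
  expect_equal(m1$ratio, (3e11 / 794 / 100)^0.43, tolerance = 1e-12)
  expect_equal(extrapolate_ratio(0)$ratio, 1)
  expect_error(extrapolate_ratio(0.5, n_syn_target = -1), "positive")
})

test_that("inverse Simpson index q measures update diversity", {
  expect_equal(update_probability_q(rep(7, 20)), 1)          # uniform
  expect_equal(update_probability_q(c(rep(5, 4), rep(0, 16))), 4 / 20) # fixed k
  expect_equal(update_probability_q(c(0.5, 0.5, 0, 0)), 0.5) # 1/(4 * 0.5)
  expect_error(update_probability_q(rep(0, 5)), "zero")
  expect_error(update_probability_q(c(-1, 2)), "negative")
  # list-of-matrices input (as returned in a train record)
  expect_equal(update_probability_q(list(A = matrix(1, 2, 2), B = matrix(1, 1, 4))), 1)
})

test_that("top-k keeps switching synapses: q well above k/N", {
  ds <- easy_ds()
  rec <- train_to_criterion(ds$train, ds$valid, n_hidden = 40,
                            config = training_config(seed = 5, max_epochs = 1,
                                                     criterion_accuracy = 1,
                                                     eval_every = 1500),
                            strategy = strategy_spec("topk", topk_fraction = 0.02,
                                                     topk_scope = "layer"),
                            track_update_counts = TRUE)
  q <- update_probability_q(rec$update_counts$W_in)
  expect_gt(q, 5 * 0.02)
  # per-iteration kept count is exact
  expect_equal(rec$ledger$per_layer$W_in$m0,
               rec$T * ceiling(0.02 * 40 * 61))
})

test_that("competitive selection preserves saturation accuracy, a fixed mask does not", {
  ds <- easy_ds()
  cfg <- training_config(seed = 5, max_epochs = 6, criterion_accuracy = 1,
                         eval_every = 1500)
  sat <- function(strategy) {
    r <- train_to_criterion(ds$train, ds$valid, n_hidden = 50, config = cfg,
                            strategy = strategy)
    utils::tail(r$accuracy_trace$accuracy, 1)
  }
  acc_full <- sat(strategy_spec("full"))
  acc_topk <- sat(strategy_spec("topk", topk_fraction = 0.02))
  acc_mask <- sat(strategy_spec("fixed_synapse_mask", f0 = 0.02, f1 = 1, seed = 2))
  expect_gte(acc_topk, acc_full - 0.01) # top-k barely drops
  expect_lt(acc_mask, acc_topk)         # same-density fixed mask loses more
})

test_that("masking removes the learning-speed benefit of larger networks", {
  ds <- hard_ds()
  cfg <- training_config(max_epochs = 15, eval_every = 500,
                         criterion_accuracy = 0.90)
  sizes <- c(60, 150, 400)
  sw_full <- energy_size_sweep(sizes, seeds = 1, ds$train, ds$valid, config = cfg)
  sw_mask <- energy_size_sweep(sizes, seeds = 1, ds$train, ds$valid, config = cfg,
    strategy_fn = function(nh) {
      opt <- optimal_fractions(mask_problem(nh, mu = 60, n_in = 80, n_out = 8))
      strategy_spec("fixed_synapse_mask", f0 = opt$f0, f1 = opt$f1, seed = 99)
    })
  slope_full <- fit_power_law(sw_full$n_hidden, sw_full$T)$exponent
  slope_mask <- fit_power_law(sw_mask$n_hidden, sw_mask$T)$exponent
  # sign constraint only: with masking T does not fall with size the way the
  # unmasked nets would allow
  expect_gte(slope_mask, slope_full)
  expect_true(all(sw_full$converged))
})

test_that("divergence at an excessive learning rate is flagged, not thrown", {
  ds <- easy_ds()
  cfg <- training_config(learning_rate = 50, seed = 1, max_epochs = 1,
                         eval_every = 1500, criterion_accuracy = 1)
  rec <- train_to_criterion(ds$train, ds$valid, n_hidden = 10, config = cfg)
  expect_true(rec$diverged)
  expect_false(rec$converged)
})

test_that("run summaries flatten into sweep rows", {
  ds <- easy_ds()
  sw <- energy_size_sweep(c(6, 10), seeds = c(1, 2), ds$train, ds$valid,
                          config = training_config(max_epochs = 1,
                                                   criterion_accuracy = 1,
                                                   eval_every = 750))
  expect_equal(nrow(sw), 4)
  expect_setequal(unique(sw$n_hidden), c(6, 10))
  expect_true(all(c("T", "m0", "m1", "W_in_m0", "final_accuracy") %in% names(sw)))
  # accuracy trace carries ledger snapshots at every evaluation
  rec <- train_to_criterion(ds$train, ds$valid, n_hidden = 6,
                            config = training_config(max_epochs = 1,
                                                     criterion_accuracy = 1,
                                                     eval_every = 500))
  expect_equal(rec$accuracy_trace$samples_seen, c(500L, 1000L, 1500L))
  expect_true(all(diff(rec$accuracy_trace$m0) > 0))
})
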