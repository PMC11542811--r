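# build a proposal with known entries for restriction tests
proposal_of <- function(dW_in, dW_out, lr = 0.01) {
  structure(list(dW_in = dW_in, dW_out = dW_out, learning_rate = lr),
            class = "update_proposal")
}

test_that("init_strategy draws fixed structures once, deterministically", {
  spec <- strategy_spec("fixed_synapse_mask", f0 = 0.3, f1 = 0.8, seed = 5)
  a <- init_strategy(spec, n_in = 50, n_hidden = 40, n_out = 10)
  b <- init_strategy(spec, n_in = 50, n_hidden = 40, n_out = 10)
  expect_identical(a$mask_in, b$mask_in)
  expect_identical(a$mask_out, b$mask_out)
  expect_equal(dim(a$mask_in), c(40L, 51L))
  expect_equal(dim(a$mask_out), c(10L, 41L))

  # mask density within the binomial 99% CI of f0
  n <- length(a$mask_in)
  ci <- qnorm(c(0.005, 0.995), mean = n * 0.3, sd = sqrt(n * 0.3 * 0.7))
  expect_gt(sum(a$mask_in), ci[1])
  expect_lt(sum(a$mask_in), ci[2])

  # f = 1 gives all-ones masks
  s1 <- init_strategy(strategy_spec("fixed_synapse_mask", f0 = 1, f1 = 1, seed = 1),
                      10, 8, 3)
  expect_true(all(s1$mask_in == 1) && all(s1$mask_out == 1))

  # subnet with S = N_h is the full hidden layer
  sn <- init_strategy(strategy_spec("subnet", subnet_size = 8, seed = 1), 10, 8, 3)
  expect_equal(sn$plastic_units, 1:8)
  expect_error(init_strategy(strategy_spec("subnet", subnet_size = 9, seed = 1),
                             10, 8, 3), "exceeds")
})

test_that("top-k keeps exactly the largest-magnitude input-layer updates", {
  dW_in <- matrix(c(0.3, -0.5, 0.1, -0.05), 1, 4)
  dW_out <- matrix(c(1, 2), 1, 2)
  st <- init_strategy(strategy_spec("topk", topk_fraction = 0.5), 3, 1, 1)
  r <- restrict_proposal(st, proposal_of(dW_in, dW_out))
  expect_equal(r$dW_in, matrix(c(0.3, -0.5, 0, 0), 1, 4))
  expect_identical(r$dW_out, dW_out) # output layer always updated

  # fraction 1 is the identity
  st1 <- init_strategy(strategy_spec("topk", topk_fraction = 1), 3, 1, 1)
  p <- proposal_of(dW_in, dW_out)
  expect_identical(restrict_proposal(st1, p), p)

  # exact count under ties, deterministic lowest-index tie-break
  tied <- matrix(c(0.2, -0.2, 0.2, -0.2, 0.2, 0.2), 2, 3)
  sttie <- init_strategy(strategy_spec("topk", topk_fraction = 0.5), 2, 2, 1)
  rt <- restrict_proposal(sttie, proposal_of(tied, matrix(1, 1, 3)))
  expect_equal(sum(rt$dW_in != 0), ceiling(0.5 * 6))
  expect_equal(which(rt$dW_in != 0), 1:3) # first flat indices win

  # neuron scope: the rule applies within each row
  m <- rbind(c(5, 1, -2, 0.5), c(0.1, -4, 3, 0.2))
  stn <- init_strategy(strategy_spec("topk", topk_fraction = 0.5,
                                     topk_scope = "neuron"), 3, 2, 1)
  rn <- restrict_proposal(stn, proposal_of(m, matrix(1, 1, 3)))
  expect_equal(rn$dW_in, rbind(c(5, 0, -2, 0), c(0, -4, 3, 0)))
})

test_that("neuron mask and subnet zero the correct rows/columns", {
  dW_in <- matrix(1:6, 2, 3) * 0.1
  dW_out <- matrix(1:6, 2, 3) * 0.1 # n_out=2, n_hidden=2 (+bias col)
  spec <- strategy_spec("subnet", subnet_size = 1, seed = 3)
  st <- init_strategy(spec, 2, 2, 2)
  st$plastic_units <- 1L # pin for the assertion
  r <- restrict_proposal(st, proposal_of(dW_in, dW_out))
  expect_equal(r$dW_in[2, ], rep(0, 3))
  expect_equal(r$dW_in[1, ], dW_in[1, ])
  expect_equal(r$dW_out[, 2], rep(0, 2)) # frozen unit's outgoing column
  expect_equal(r$dW_out[, 3], dW_out[, 3]) # output bias stays plastic

  # neuron mask leaves the output layer untouched
  stn <- init_strategy(strategy_spec("fixed_neuron_mask", subnet_size = 1,
                                     seed = 3), 2, 2, 2)
  stn$plastic_units <- 1L
  rn <- restrict_proposal(stn, proposal_of(dW_in, dW_out))
  expect_identical(rn$dW_out, dW_out)
  expect_equal(rn$dW_in[2, ], rep(0, 3))
})

test_that("fixed restrictions are projections with constant support", {
  set.seed(20)
  p <- proposal_of(matrix(rnorm(40), 4, 10), matrix(rnorm(15), 3, 5))
  for (spec in list(strategy_spec("fixed_synapse_mask", f0 = 0.4, f1 = 0.6, seed = 2),
                    strategy_spec("fixed_neuron_mask", subnet_size = 2, seed = 2),
                    strategy_spec("subnet", subnet_size = 2, seed = 2))) {
    st <- init_strategy(spec, 9, 4, 3)
    once <- restrict_proposal(st, p)
    twice <- restrict_proposal(st, once)
    expect_identical(twice, once)
    # support is constant across calls with different proposals
    p2 <- proposal_of(matrix(rnorm(40), 4, 10), matrix(rnorm(15), 3, 5))
    r2 <- restrict_proposal(st, p2)
    expect_identical(r2$dW_in == 0 | p2$dW_in == 0, once$dW_in == 0 | p$dW_in == 0)
  }
})

test_that("dropconnect draws fresh or per-class-persistent masks", {
  set.seed(6)
  p <- proposal_of(matrix(1, 5, 8), matrix(1, 3, 6))
  st <- init_strategy(strategy_spec("dropconnect", f0 = 0.5), 7, 5, 3)
  r1 <- restrict_proposal(st, p)
  r2 <- restrict_proposal(st, p)
  expect_false(identical(r1$dW_in, r2$dW_in)) # fresh masks each call
  expect_true(all(r1$dW_in %in% c(0, 1)))

  stc <- init_strategy(strategy_spec("dropconnect", f0 = 0.5, per_class = TRUE),
                       7, 5, 3)
  c1 <- restrict_proposal(stc, p, sample_label = 2L)
  c2 <- restrict_proposal(stc, p, sample_label = 2L)
  expect_identical(c1, c2) # persistent per class
  c3 <- restrict_proposal(stc, p, sample_label = 0L)
  expect_false(identical(c1$dW_in, c3$dW_in))
  expect_error(restrict_proposal(stc, p), "sample_label")
})

test_that("exploratory neuron-level selection keeps the strongest rows", {
  p <- proposal_of(matrix(1, 4, 3), matrix(1, 2, 5))
  spec <- strategy_spec("topk", topk_fraction = 0.5,
                        selection_metric = "neuron_error")
  st <- init_strategy(spec, 2, 4, 2)
  r <- restrict_proposal(st, p, hidden_errors = c(0.1, -3, 2, 0.5))
  expect_equal(which(rowSums(abs(r$dW_in)) > 0), c(2L, 3L))

  speca <- strategy_spec("topk", topk_fraction = 0.25,
                         selection_metric = "neuron_activity")
  sta <- init_strategy(speca, 2, 4, 2)
  ra <- restrict_proposal(sta, p, hidden_activities = c(0.1, -3, 2, 0.5))
  expect_equal(which(rowSums(abs(ra$dW_in)) > 0), 2L)
  expect_error(restrict_proposal(sta, p), "hidden_activities")
})

test_that("top-k within a subnet freezes the complement in both layers", {
  set.seed(12)
  p <- proposal_of(matrix(rnorm(50), 5, 10), matrix(rnorm(18), 3, 6))
  spec <- strategy_spec("topk", topk_fraction = 0.2, subnet_size = 2, seed = 4)
  st <- init_strategy(spec, 9, 5, 3)
  r <- restrict_proposal(st, p)
  frozen <- setdiff(1:5, st$plastic_units)
  expect_true(all(r$dW_in[frozen, ] == 0))
  expect_true(all(r$dW_out[, frozen] == 0))
  expect_equal(r$dW_out[, 6], p$dW_out[, 6]) # bias column survives
  # selection count is over subnet entries only
  expect_equal(sum(r$dW_in != 0), ceiling(0.2 * 2 * 10))
})
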