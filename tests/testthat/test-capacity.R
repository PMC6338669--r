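test_that("Blahut-Arimoto matches closed-form capacities", {
  for (p in c(0.05, 0.11, 0.2, 0.5)) {
    est <- blahut_arimoto(make_reference_channel("bsc", p = p))
    expect_lt(abs(est$cc_bits - (1 - H2(p))), 1e-6)
    expect_true(est$converged)
    # symmetric channel: uniform optimal input
    expect_equal(unname(est$optimal_input), c(0.5, 0.5), tolerance = 1e-6)
  }
  # noiseless k-ary channel: log2(k)
  expect_equal(blahut_arimoto(make_reference_channel("identity", k = 2))$cc_bits, 1.0)
  expect_lt(abs(blahut_arimoto(make_reference_channel("identity", k = 4))$cc_bits - 2), 1e-9)
  # binary erasure channel: 1 - p
  expect_lt(abs(blahut_arimoto(make_reference_channel("erasure", p = 0.3))$cc_bits - 0.7), 1e-6)
  # indistinguishable inputs: zero capacity
  flat <- matrix(c(0.4, 0.6, 0.4, 0.6), 2, 2, byrow = TRUE)
  expect_equal(blahut_arimoto(flat)$cc_bits, 0)
})

test_that("Blahut-Arimoto respects capacity bounds and permutation invariance", {
  set.seed(17)
  for (i in 1:5) {
    k <- sample(3:6, 1); m <- sample(4:10, 1)
    W <- matrix(rgamma(k * m, 1), k, m); W <- W / rowSums(W)
    est <- blahut_arimoto(W)
    expect_lte(est$cc_bits, log2(k) + 1e-9)
    expect_gte(est$cc_bits, 0)
    expect_equal(sum(est$optimal_input), 1, tolerance = 1e-9)
    expect_true(all(est$optimal_input >= 0))
    expect_equal(est$distinguishable_states, 2^est$cc_bits)
    # permuting output bins or input rows leaves capacity unchanged
    perm_out <- blahut_arimoto(W[, sample(m)])
    perm_in <- blahut_arimoto(W[sample(k), ])
    expect_equal(perm_out$cc_bits, est$cc_bits, tolerance = 1e-7)
    expect_equal(perm_in$cc_bits, est$cc_bits, tolerance = 1e-7)
  }
  expect_error(blahut_arimoto(matrix(c(0.5, 0.4, 0.2, 0.8), 2, 2)),
               "validation error")
})

test_that("discretization yields a valid row-stochastic channel", {
  cells <- small_cells(n_cells = 400, seed = 19)
  ch <- build_discrete_channel(channel_dataset(cells))
  # equal-frequency edges merge over the point mass of zero responses at
  # dose 0, so the bin count can drop below the request
  expect_equal(nrow(ch$transition), 12L)
  expect_lte(ncol(ch$transition), 20L)
  expect_gte(ncol(ch$transition), 10L)
  expect_equal(unname(rowSums(ch$transition)), rep(1, 12), tolerance = 1e-12)
  expect_true(all(ch$transition > 0))   # pseudocount smoothing

  # two fully separated response distributions, 2 bins: near-identity
  sep <- cell_table(expression = rep(100, 200),
                    response = c(runif(100, 1, 2), runif(100, 10, 20)),
                    dose = rep(c(0, 25), each = 100))
  ch2 <- build_discrete_channel(channel_dataset(sep), bins = 2)
  expect_gt(ch2$transition[1, 1], 0.98)
  expect_gt(ch2$transition[2, 2], 0.98)

  # identical response distributions: rows equal up to sampling noise
  set.seed(23)
  same <- cell_table(expression = rep(100, 4000),
                     response = rlnorm(4000, 1, 0.3),
                     dose = rep(c(0, 25), each = 2000))
  ch3 <- build_discrete_channel(channel_dataset(same), bins = 10)
  expect_lt(max(abs(ch3$transition[1, ] - ch3$transition[2, ])), 0.05)
})

test_that("classifier capacity recovers analytic channels", {
  # two well-separated Gaussian responses: a clean 1-bit channel
  set.seed(29)
  n <- 2000
  sep <- cell_table(expression = rep(100, 2 * n),
                    response = c(rnorm(n, -5), rnorm(n, 5)),
                    dose = rep(c(0, 25), each = n))
  est <- estimate_cc_classifier(channel_dataset(sep), transform = "none")
  expect_lt(abs(est$cc_bits - 1), 0.02)
  expect_true(est$converged)

  # all levels from one distribution: essentially no information
  null <- cell_table(expression = rep(100, 2 * n),
                     response = rnorm(2 * n, 3, 1),
                     dose = rep(c(0, 25), each = n))
  null_est <- estimate_cc_classifier(channel_dataset(null), transform = "none")
  expect_lte(null_est$cc_bits, 0.05)
})

test_that("classifier and discretized Blahut-Arimoto agree on 1-D channels", {
  set.seed(37)
  n <- 1000
  mk <- function(mu) rlnorm(n, mu, 0.35)
  cells <- cell_table(expression = rep(100, 4 * n),
                      response = c(mk(0.5), mk(1.2), mk(1.9), mk(2.6)),
                      dose = rep(c(0, 1, 10, 100), each = n))
  ds <- channel_dataset(cells)
  cls <- estimate_cc_classifier(ds)
  ba <- blahut_arimoto(build_discrete_channel(ds, bins = 20))
  expect_lt(abs(cls$cc_bits - ba$cc_bits), 0.1)
})

test_that("capacity entry points validate their inputs", {
  one_level <- cell_table(expression = runif(50, 50, 150),
                          response = runif(50), dose = 25)
  expect_error(capacity_basic(channel_dataset(one_level)), ">= 2 input")
  expect_error(capacity_var(channel_dataset(one_level)), ">= 2 input")

  # a noiseless channel where the response encodes the dose index exactly
  doses <- c(0, 0.5, 1, 2.5, 5, 10, 15, 25, 50, 75, 100, 200)
  det <- cell_table(expression = rep(100, 12 * 50),
                    response = rep(seq_along(doses), each = 50),
                    dose = rep(doses, each = 50))
  est <- capacity_basic(channel_dataset(det), bins = 12, pseudocount = 0)
  expect_lt(abs(est$cc_bits - log2(12)), 1e-6)
})

test_that("conditioning on expression never loses information (classifier)", {
  cells <- one_replicate(small_cells(n_cells = 800, seed = 41))
  ds <- channel_dataset(cells)
  basic <- estimate_cc_classifier(ds, response_features = "response")
  var <- estimate_cc_classifier(ds, response_features = c("response", "expression"))
  expect_gte(var$cc_bits, basic$cc_bits - 0.02)
})

test_that("an uninformative covariate does not inflate capacity", {
  cells <- one_replicate(small_cells(n_cells = 800, seed = 43))
  # make expression independent of response within each dose
  for (idx in split(seq_len(nrow(cells)), cells$dose)) {
    set.seed(idx[1])
    cells$expression[idx] <- cells$expression[sample(idx)]
  }
  ds <- channel_dataset(cells)
  basic <- estimate_cc_classifier(ds, response_features = "response")
  var <- estimate_cc_classifier(ds, response_features = c("response", "expression"))
  expect_lte(var$cc_bits - basic$cc_bits, 0.05)
})

test_that("the truncation sweep reports per-replicate capacities and skips", {
  cells <- small_cells(n_cells = 400, n_replicates = 2, seed = 47)
  sw <- suppressWarnings(
    truncation_capacity_sweep(cells, residuals = c(1, 0.5),
                              min_cells = 1000L))
  expect_s3_class(sw, "capacity_sweep")
  expect_equal(nrow(sw), 4L)
  full <- sw[sw$residual == 1, ]
  expect_true(all(!full$skipped))
  # residual 0.5 of 4800 cells/replicate = 2400 >= min_cells: computed
  expect_true(all(!sw$skipped[sw$residual == 0.5]))
  # residual 1.0 equals capacity on untruncated data
  ds <- channel_dataset(one_replicate(cells))
  expect_equal(full$cc_basic[full$replicate == "1"],
               capacity_basic(ds)$cc_bits, tolerance = 1e-9)
  # a residual too small for min_cells is marked skipped
  sw2 <- suppressWarnings(
    truncation_capacity_sweep(cells, residuals = c(0.05), min_cells = 1000L))
  expect_true(all(sw2$skipped))
})
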