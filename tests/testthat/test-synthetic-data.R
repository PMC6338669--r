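test_that("generation is exactly reproducible and stream-split by stratum", {
  cfg <- sim_config(n_cells = 100, n_replicates = 2, seed = 5)
  a <- simulate_cells(cfg)
  b <- simulate_cells(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))

  # adding a dose level does not perturb the other strata
  c1 <- simulate_cells(sim_config(n_cells = 100, doses = c(0, 25),
                                  n_replicates = 1, seed = 5))
  c2 <- simulate_cells(sim_config(n_cells = 100, doses = c(0, 10, 25),
                                  n_replicates = 1, seed = 5))
  expect_identical(c1$response[c1$dose == 25], c2$response[c2$dose == 25])
  expect_identical(c1$expression[c1$dose == 0], c2$expression[c2$dose == 0])
})

test_that("the generator produces a saturating dose-response", {
  cfg <- sim_config(n_cells = 2000, n_replicates = 1, seed = 11)
  cells <- simulate_cells(cfg)
  expect_equal(nrow(cells), 2000L * 12L)
  means <- tapply(cells$response, cells$dose, mean)
  doses <- as.numeric(names(means))
  # strictly increasing through the rising phase, saturating at the top
  rising <- means[doses <= 50]
  expect_true(all(diff(rising) > 0))
  expect_lt(means[doses == 200] / means[doses == 100], 1.1)
  # ground truth is attached but never consumed by estimators
  gt <- attr(cells, "ground_truth")
  expect_equal(nrow(gt), nrow(cells))
  expect_true(all(gt$P >= 0))
})

test_that("scenario knobs are pure parameter transforms", {
  base <- simulate_cells(sim_config(n_cells = 2000, doses = 25,
                                    n_replicates = 1, seed = 7))
  hi <- simulate_cells(sim_config(n_cells = 2000, doses = 25,
                                  n_replicates = 1, seed = 7,
                                  scenario = "STAT3high"))
  # 3-fold mean overexpression on the log scale
  expect_equal(median(hi$expression) / median(base$expression), 3,
               tolerance = 0.1)

  # feedback attenuates the late response; its knockout does not
  mef90 <- simulate_cells(sim_config(n_cells = 2000, doses = 25,
                                     n_replicates = 1, seed = 7, time = 90))
  ko90 <- simulate_cells(sim_config(n_cells = 2000, doses = 25,
                                    n_replicates = 1, seed = 7, time = 90,
                                    scenario = "SOCS3ko"))
  expect_lt(mean(mef90$response), 0.7 * mean(base$response))
  expect_equal(mean(ko90$response), mean(base$response), tolerance = 0.05)

  # S727A-type gain raises the mean response beyond overexpression alone
  s727 <- simulate_cells(sim_config(n_cells = 2000, doses = 25,
                                    n_replicates = 1, seed = 7,
                                    scenario = "S727Ahigh"))
  expect_gt(mean(s727$response), 1.5 * mean(hi$response))
})

test_that("a noise-dominated generator destroys expression-response coupling", {
  cfg <- sim_config(n_cells = 2000, doses = c(5, 200), n_replicates = 1,
                    seed = 13, sigma_b = 1e5)
  cells <- simulate_cells(cfg)
  for (d in c(5, 200)) {
    sub <- cells[cells$dose == d, ]
    est <- estimate_mi_plugin(sub$expression, sub$response, 10, 10,
                              correction = "miller_madow")
    expect_lte(est$mi_bits, 0.05)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_cells = 0), "parameter error")
  expect_error(sim_config(doses = c(-1, 5)), "parameter error")
  expect_error(sim_config(expression_sigma = 0), "parameter error")
  expect_error(sim_config(time = 30), "parameter error")
  expect_error(simulate_cells(list(n_cells = 10)), "sim_config")
})

test_that("reference channels match their definitions", {
  bsc <- make_reference_channel("bsc", p = 0.11)
  expect_equal(bsc$transition,
               matrix(c(0.89, 0.11, 0.11, 0.89), 2, 2, byrow = TRUE),
               ignore_attr = TRUE)
  expect_equal(make_reference_channel("identity", k = 4)$transition, diag(4),
               ignore_attr = TRUE)
  er <- make_reference_channel("erasure", p = 0.2)
  expect_equal(rowSums(er$transition), c(1, 1), ignore_attr = TRUE)
  gp <- make_reference_channel("gaussian_pair", rho = 0.9, n = 5000, seed = 3)
  expect_lt(abs(cor(gp$x, gp$y) - 0.9), 0.02)
  expect_error(make_reference_channel("bsc", p = 1.2), "parameter error")
})

test_that("CSV fixtures round-trip exactly through the loader", {
  cells <- one_replicate(small_cells(n_cells = 100, seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_fixture(cells, path, format = "csv")
  back <- load_cells(path)
  expect_equal(back$expression, cells$expression)
  expect_equal(back$response, cells$response)
  expect_equal(back$dose, cells$dose)
})
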