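test_that("the Gaussian closed form evaluates -1/2 log2(1 - rho^2)", {
  expect_equal(mi_gaussian_closed_form(0), 0)
  expect_equal(mi_gaussian_closed_form(0.9), -0.5 * log2(0.19))
  expect_equal(mi_gaussian_closed_form(-0.9), mi_gaussian_closed_form(0.9))
  expect_error(mi_gaussian_closed_form(1), "parameter error")
})

test_that("KDE MI tracks the bivariate-Gaussian closed form", {
  for (rho in c(0, 0.5, 0.9)) {
    gp <- make_reference_channel("gaussian_pair", rho = rho, n = 2000,
                                 seed = 7)
    est <- estimate_mi_kde(gp$x, gp$y, integrator = "fixed_grid")
    expect_lt(abs(est$mi_bits - mi_gaussian_closed_form(rho)), 0.08)
    expect_equal(est$n_cells, 2000L)
    # Scott bandwidths: per-coordinate sd * n^(-1/6)
    expect_equal(est$bandwidth_x, sd(gp$x) * 2000^(-1 / 6))
  }
})

test_that("fixed-grid and adaptive quadrature integrators agree", {
  gp <- make_reference_channel("gaussian_pair", rho = 0.7, n = 600, seed = 3)
  grid <- estimate_mi_kde(gp$x, gp$y, integrator = "fixed_grid")
  quad <- estimate_mi_kde(gp$x, gp$y, integrator = "adaptive_quadrature")
  expect_lt(abs(grid$mi_bits - quad$mi_bits), 0.01)
  expect_gte(quad$integration_error, 0)
})

test_that("KDE MI is symmetric and approximately affine-invariant", {
  gp <- make_reference_channel("gaussian_pair", rho = 0.6, n = 1000, seed = 9)
  a <- estimate_mi_kde(gp$x, gp$y, integrator = "fixed_grid")
  b <- estimate_mi_kde(gp$y, gp$x, integrator = "fixed_grid")
  expect_equal(a$mi_bits, b$mi_bits, tolerance = 1e-6)
  c <- estimate_mi_kde(10 + 3 * gp$x, 100 * gp$y, integrator = "fixed_grid")
  expect_lt(abs(a$mi_bits - c$mi_bits), 0.05)
})

test_that("degenerate inputs are rejected", {
  expect_error(estimate_mi_kde(rep(1, 100), rnorm(100)), "degenerate-density")
  expect_error(estimate_mi_kde(rnorm(10), rnorm(10)), "at least 20")
  expect_error(fit_kde_joint(rep(2, 50), rnorm(50)), "degenerate-density")
})

test_that("the joint KDE marginals integrate to one over the support", {
  set.seed(12)
  k <- fit_kde_joint(rnorm(500), rnorm(500))
  gx <- seq(k$support["xmin"], k$support["xmax"], length.out = 2000)
  dx <- gx[2] - gx[1]
  expect_equal(sum(k$marginal_x(gx)) * dx, 1, tolerance = 1e-3)
  gy <- seq(k$support["ymin"], k$support["ymax"], length.out = 2000)
  expect_equal(sum(k$marginal_y(gy)) * (gy[2] - gy[1]), 1, tolerance = 1e-3)
})

test_that("plug-in MI matches direct contingency-table computation", {
  # deterministic bijection over balanced bins: exactly log2(bins)
  x <- seq_len(1000)
  det <- estimate_mi_plugin(x, x, bins_x = 10, bins_y = 10)
  expect_equal(det$mi_bits, log2(10), tolerance = 1e-12)

  # pre-binned 2x2 diagonal counts {{50,0},{0,50}}: exactly 1 bit
  xb <- rep(c(0, 1), each = 50)
  expect_equal(estimate_mi_plugin(xb, xb, 2, 2)$mi_bits, 1.0)

  # discrete pre-binned data: agree exactly with the entropy-based oracle
  set.seed(5)
  x <- sample(1:4, 500, replace = TRUE)
  y <- (x + sample(0:1, 500, replace = TRUE)) %% 4
  est <- estimate_mi_plugin(x, y, 4, 4)
  expect_equal(est$mi_bits, mi_from_table(table(x, y)), tolerance = 1e-12)
})

test_that("plug-in MI bias stays bounded on independent data", {
  set.seed(6)
  est <- estimate_mi_plugin(runif(10000), runif(10000), 10, 10)
  expect_gte(est$mi_bits, 0)
  expect_lte(est$mi_bits, 0.05)
  mm <- estimate_mi_plugin(runif(10000), runif(10000), 10, 10,
                           correction = "miller_madow")
  expect_lt(abs(mm$mi_bits), 0.01)
  expect_error(estimate_mi_plugin(1:10, 1:10, bins_x = 1), "parameter error")
})

test_that("plug-in MI is exactly invariant under monotone rescaling", {
  set.seed(8)
  x <- rlnorm(400); y <- x * exp(rnorm(400, 0, 0.3))
  a <- estimate_mi_plugin(x, y, 6, 6)
  b <- estimate_mi_plugin(log(x), sqrt(y), 6, 6)
  expect_equal(a$mi_bits, b$mi_bits)
})

test_that("negative MI estimates are flagged invalid, not clamped", {
  est <- cytoinfo:::new_mi_estimate(mi_bits = -0.012, estimator = "kde_grid")
  expect_false(est$valid)
  expect_equal(est$mi_bits, -0.012)   # raw value retained
  pos <- cytoinfo:::new_mi_estimate(mi_bits = 0.4, estimator = "kde_grid")
  expect_true(pos$valid)
})

test_that("sweep aggregation excludes invalid estimates from summaries", {
  rows <- data.frame(
    replicate = rep(c("1", "2", "3"), 2),
    dose = rep(c(10, 25), each = 3),
    mi_bits = c(0.5, 0.6, -0.05, 0.8, 0.82, 0.78),
    valid = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))
  s <- summarize_mi_sweep(rows)
  expect_equal(s$n_excluded, c(1L, 0L))
  expect_equal(s$mi_median[s$dose == 10], median(c(0.5, 0.6)))
  expect_equal(s$n_replicates, c(2L, 3L))
})

test_that("the dose sweep skips small strata and reports the rest", {
  cells <- small_cells(n_cells = 300, n_replicates = 2, seed = 13)
  # shrink one stratum below min_cells
  drop <- which(cells$dose == 25 & cells$replicate == "1")[-(1:5)]
  cells <- cells[-drop, , drop = FALSE]
  class(cells) <- c("cell_table", "data.frame")
  expect_warning(sw <- mi_dose_sweep(cells, min_cells = 100), "skipped")
  expect_false(any(sw$dose == 25 & sw$replicate == "1"))
  expect_true(any(sw$dose == 25 & sw$replicate == "2"))
  # dose 0 is a baseline diagnostic, not part of the sweep
  expect_false(any(sw$dose == 0))
  expect_true(!is.null(attr(sw, "baseline")))
})

test_that("a response independent of expression gives near-zero MI everywhere", {
  cfg <- sim_config(n_cells = 2000, n_replicates = 1,
                    doses = c(5, 50), seed = 31)
  cells <- simulate_cells(cfg)
  # break the coupling: permute responses within each stratum
  for (idx in split(seq_len(nrow(cells)),
                    paste(cells$dose, cells$replicate))) {
    set.seed(idx[1])
    cells$response[idx] <- cells$response[sample(idx)]
  }
  sw <- mi_dose_sweep(cells, min_cells = 100)
  expect_true(all(abs(summary(sw)$mi_median) < 0.08))
})
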