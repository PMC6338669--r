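test_that("cell_table enforces its schema and invariants", {
  ct <- cell_table(expression = c(90, 110), response = c(5, 10), dose = 25)
  expect_s3_class(ct, "cell_table")
  expect_equal(nrow(ct), 2L)
  expect_error(cell_table(c(1, NA), c(1, 2), 0), "non-finite")
  expect_error(cell_table(1, 2, dose = -1), "negative dose")
  expect_error(as_cell_table(data.frame(expression = numeric(0),
                                        response = numeric(0))),
               "empty-data")
})

test_that("CSV load/write round-trips exactly and drops non-finite events", {
  cells <- small_cells(n_cells = 50)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cells(cells, path)
  back <- load_cells(path)
  expect_equal(back$expression, cells$expression)
  expect_equal(back$response, cells$response)
  expect_equal(back$dose, cells$dose)
  expect_equal(attr(back, "dropped"), 0L)

  # inject a NaN response: that row is dropped and counted
  raw <- read.csv(path)
  raw$response[3] <- NaN
  write.csv(raw, path, row.names = FALSE)
  back2 <- load_cells(path)
  expect_equal(nrow(back2), nrow(cells) - 1L)
  expect_equal(attr(back2, "dropped"), 1L)
})

test_that("load_cells maps raw channel names and metadata columns", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(STAT3 = c(100, 120, 90), pSTAT3 = c(4, 8, 6),
                       dose = 25), path, row.names = FALSE)
  ct <- load_cells(path, channel_map = c(expression = "STAT3",
                                         response = "pSTAT3"),
                   metadata = list(time = 15, replicate = "r1", line = "MEF"))
  expect_equal(nrow(ct), 3L)
  expect_equal(ct$dose, rep(25, 3))
  expect_equal(ct$expression, c(100, 120, 90))
  expect_error(load_cells(path, channel_map = c(expression = "nope",
                                                response = "pSTAT3")),
               "schema error")
  expect_error(load_cells(withr::local_tempfile(fileext = ".xyz")),
               "not found")
})

test_that("normalization scales the maximal per-dose mean to 100%", {
  # three dose groups with mean responses 50, 80, 100 -> already peaked at 100
  mk <- function(means) {
    do.call(rbind, lapply(seq_along(means), function(i)
      data.frame(expression = rep(10, 4), response = rep(means[i], 4),
                 dose = i, time = 15, replicate = "1", line = "MEF")))
  }
  ct <- as_cell_table(mk(c(50, 80, 100)))
  nm <- normalize_experiment(ct)
  expect_equal(as.vector(tapply(nm$response, nm$dose, mean)), c(50, 80, 100))

  ct2 <- as_cell_table(mk(c(40, 200)))
  nm2 <- normalize_experiment(ct2)
  expect_equal(as.vector(tapply(nm2$response, nm2$dose, mean)), c(20, 100))
  expect_true(all(nm2$response_raw %in% c(40, 200)))

  # single dose group: its mean becomes 100
  ct3 <- as_cell_table(mk(7))
  expect_equal(mean(normalize_experiment(ct3)$response), 100)
})

test_that("normalization is idempotent and rejects all-zero responses", {
  cells <- small_cells(n_cells = 100)
  once <- normalize_experiment(cells)
  twice <- normalize_experiment(once)
  expect_equal(twice$response, once$response, tolerance = 1e-12)
  expect_equal(twice$expression, once$expression, tolerance = 1e-12)

  zero <- cells
  zero$response <- 0
  expect_error(normalize_experiment(zero), "degenerate-normalization")
})
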