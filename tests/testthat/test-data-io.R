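# Reading, writing and normalizing time-series tables; reference PPI sets.

test_that("well-formed tables round-trip exactly and invariants are enforced", {
  set.seed(4)
  vals <- matrix(rnorm(3 * 13), 3)
  ts <- make_ts(vals, proteins = c("P1", "P2;P3", "P4"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_timeseries(ts, path, params = list(note = "fixture"))
  back <- read_timeseries(path)
  expect_identical(back$peptide_id, ts$peptide_id)
  expect_identical(back$protein_id, ts$protein_id)
  expect_identical(unname(back$values), unname(ts$values))
  expect_identical(back$time_grid, ts$time_grid)
  expect_setequal(proteins(ts), c("P1", "P2", "P3", "P4"))

  expect_error(ts_matrix(c("a", "a"), c("p", "q"), matrix(0, 2, 13)),
               "duplicate")
  expect_error(make_ts(matrix(rnorm(2 * 13), 2), grid = rep(1, 13)),
               "strictly increasing")
  expect_error(ts_matrix("a", "p", matrix(NA_real_, 1, 13)), "finite")
})

test_that("malformed tables fail with named columns, rows and values", {
  path <- withr::local_tempfile(fileext = ".tsv")
  hdr12 <- paste(c("peptide", "protein", paste0("t", 1:12)), collapse = "\t")
  writeLines(c(hdr12, paste(c("a", "p", rep("0.1", 12)), collapse = "\t")),
             path)
  expect_error(read_timeseries(path), "13 time columns")

  hdr <- paste(c("peptide", "protein",
                 paste0("t", format(default_time_grid(), trim = TRUE))),
               collapse = "\t")
  writeLines(c(sub("protein", "acc", hdr),
               paste(c("a", "p", rep("0.1", 13)), collapse = "\t")), path)
  expect_error(read_timeseries(path), "'protein'")

  writeLines(c(hdr, paste(c("a", "p", "oops", rep("0.1", 12)),
                          collapse = "\t")), path)
  expect_error(read_timeseries(path), "row 1")

  writeLines(c(hdr,
               paste(c("a", "p", rep("0.1", 13)), collapse = "\t"),
               paste(c("b", "q", "", rep("0.2", 12)), collapse = "\t")),
             path)
  expect_message(back <- read_timeseries(path), "1 row")
  expect_identical(attr(back, "n_dropped"), 1L)
  expect_identical(back$peptide_id, "a")
})

test_that("baseline normalization follows the chosen method and drops bad baselines", {
  grid3 <- 1:3
  raw <- data.frame(peptide = c("a", "b", "c"), protein = c("P", "Q", "R"),
                    v0 = c(2, 2, 0), v1 = c(4, 2, 1), v2 = c(1, 4, 2),
                    v3 = c(8, 6, 3))
  out <- suppressMessages(
    normalize_to_baseline(raw[1, ], method = "log2_ratio", time_grid = grid3))
  expect_equal(unname(out$values[1, 1:2]), c(1, -1))

  out <- normalize_to_baseline(raw[2, ], method = "difference",
                               time_grid = grid3)
  expect_equal(unname(out$values[1, ]), c(0, 2, 4))

  expect_message(
    out <- normalize_to_baseline(raw, method = "ratio", time_grid = grid3),
    "dropped")
  expect_identical(attr(out, "dropped_rows"), "c")
  expect_identical(out$peptide_id, c("a", "b"))
})

test_that("reference PPI sets deduplicate, drop self-pairs and stay symmetric", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("P1\tP2", "P2\tP1", "P1\tP1", "P3\tP4"), path)
  ref <- read_ppi_reference(path, "two_column_tsv")
  expect_identical(length(ref$keys), 2L)
  expect_identical(ref$n_self_discarded, 1L)
  expect_true(ppi_contains(ref, "P1", "P2"))
  expect_identical(ppi_contains(ref, "P1", "P2"), ppi_contains(ref, "P2", "P1"))
  expect_false(ppi_contains(ref, "P1", "P3"))
  expect_setequal(ref$universe, c("P1", "P2", "P3", "P4"))

  mitab <- withr::local_tempfile(fileext = ".txt")
  extra <- paste(rep("-", 13), collapse = "\t")
  writeLines(paste("uniprotkb:P41236", "uniprotkb:O00479", extra, sep = "\t"),
             mitab)
  ref2 <- read_ppi_reference(mitab, "mitab25")
  expect_true(ppi_contains(ref2, "O00479", "P41236"))

  writeLines(c("P1\tP2", "lonely"), path)
  expect_error(read_ppi_reference(path, "two_column_tsv"), "line 2")
})
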