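write_tmp <- function(lines, ext = "csv") {
  f <- tempfile(fileext = paste0(".", ext))
  writeLines(lines, f)
  f
}

test_that("delimited matrices parse with header and row-name detection", {
  m <- read_matrix(write_tmp(c("a,b", "1,2", "3,4")))
  expect_equal(unname(m), rbind(c(1, 2), c(3, 4)))
  expect_equal(colnames(m), c("a", "b"))
  # no header
  m2 <- read_matrix(write_tmp(c("1,2", "3,4")))
  expect_equal(unname(m2), rbind(c(1, 2), c(3, 4)))
  expect_equal(colnames(m2), c("feature_1", "feature_2"))
  # header + row names (R-style short header)
  m3 <- read_matrix(write_tmp(c("g1,g2", "c1,1,2", "c2,3,4")))
  expect_equal(rownames(m3), c("c1", "c2"))
  expect_equal(colnames(m3), c("g1", "g2"))
  # tsv by extension
  m4 <- read_matrix(write_tmp(c("1\t2", "3\t4"), "tsv"))
  expect_equal(unname(m4), rbind(c(1, 2), c(3, 4)))
})

test_that("genes-in-rows input is transposed to cells-in-rows", {
  f <- write_tmp(c("cell1,cell2,cell3", "1,2,3", "4,5,6"))
  m <- read_matrix(f, orientation = "cells_in_columns")
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(unname(m[, 1]), c(1, 2, 3))
})

test_that("malformed delimited input names the offending location", {
  expect_error(read_matrix(write_tmp(c("1,2", "3,4,5"))), "line 2")
  expect_error(read_matrix(write_tmp(c("1,2", "3,oops"))), "row 2, column 2")
  expect_error(read_matrix(write_tmp(character(0))), "empty")
  expect_error(read_matrix("no/such/file.csv"), "not found")
})

test_that("matrix market triplets densify, summing duplicates", {
  f <- write_tmp(c("%%MatrixMarket matrix coordinate real general",
                   "2 2 2", "1 1 5.0", "2 2 7.0"), "mtx")
  m <- read_matrix(f)
  expect_equal(unname(m), rbind(c(5, 0), c(0, 7)))
  fdup <- write_tmp(c("%%MatrixMarket matrix coordinate real general",
                      "2 2 3", "1 1 5.0", "1 1 2.5", "2 1 1.0"), "mtx")
  mdup <- read_matrix(fdup)
  expect_equal(unname(mdup), rbind(c(7.5, 0), c(1, 0)))
})

test_that("mtx sidecar files provide names and are length-checked", {
  f <- write_tmp(c("%%MatrixMarket matrix coordinate real general",
                   "2 3 1", "1 2 4"), "mtx")
  bc <- write_tmp(c("AAAC", "GGTT"), "txt")
  ft <- write_tmp(c("g1", "g2", "g3"), "txt")
  m <- read_matrix(f, format = "mtx", row_names_file = bc,
                   col_names_file = ft)
  expect_equal(rownames(m), c("AAAC", "GGTT"))
  expect_equal(colnames(m), c("g1", "g2", "g3"))
  expect_error(read_matrix(f, format = "mtx", row_names_file = ft),
               "3 names")
})

test_that("mtx densification agrees with a triplet-accumulation oracle", {
  set.seed(3)
  for (rep in 1:10) {
    nr <- sample(2:50, 1); nc <- sample(2:50, 1)
    nnz <- sample(1:30, 1)
    i <- sample(nr, nnz, replace = TRUE)
    j <- sample(nc, nnz, replace = TRUE)
    v <- round(runif(nnz, 0.1, 9), 3)
    f <- tempfile(fileext = ".mtx")
    writeLines(c("%%MatrixMarket matrix coordinate real general",
                 paste(nr, nc, nnz), paste(i, j, v)), f)
    expect_equal(unname(read_matrix(f)), naive_mtx_densify(i, j, v, nr, nc),
                 tolerance = 1e-12)
  }
})

test_that("label files round-trip and reject blanks", {
  f <- write_tmp(c("A", "A", "B"), "txt")
  expect_equal(read_labels(f), c("A", "A", "B"))
  # header skipping for single-column CSVs
  f2 <- write_tmp(c("cluster", "1", "2"), "csv")
  expect_equal(read_labels(f2, header = TRUE), c("1", "2"))
  # whitespace stripped
  expect_equal(read_labels(write_tmp(c("  x ", "y"), "txt")), c("x", "y"))
  expect_error(read_labels(write_tmp(c("A", "", "B"), "txt")), "line 2")
  expect_error(read_labels(write_tmp(character(0), "txt")), "empty")
  # write -> read round-trip is exact
  lf <- tempfile()
  write_labels(c("7", "noise", "7"), lf)
  expect_identical(read_labels(lf), c("7", "noise", "7"))
})

test_that("fitted results are written completely and deterministically", {
  fit <- d3k(toy_x(), k_hint = 2)
  d1 <- file.path(tempdir(), "d3k_out1")
  d2 <- file.path(tempdir(), "d3k_out2")
  paths <- write_d3k(fit, d1)
  write_d3k(fit, d2)
  lab <- readLines(file.path(d1, "labels.csv"))
  expect_length(lab, 5L)                     # header + 4 cells
  expect_equal(lab[1], "cell_id,label")
  # byte-identical report for identical fits
  expect_identical(readLines(file.path(d1, "report.json")),
                   readLines(file.path(d2, "report.json")))
  rep <- jsonlite::read_json(file.path(d1, "report.json"))
  expect_equal(rep$k, 2L)
  expect_equal(rep$T, 0.67625)
  # refuse to write an empty shell
  broken <- fit; broken$labels <- integer(0)
  expect_error(write_d3k(broken, d1), "empty")
  expect_error(write_d3k(list(), d1), "d3k object")
})
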