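test_that("packaged manifest has the expected region layout", {
  man <- pparg_manifest()
  expect_equal(nrow(man), 23)
  expect_equal(man$order_index, 1:23)
  expect_false(anyDuplicated(man$probe_id) > 0)
  expect_equal(as.vector(table(man$region)),
               c(3, 12, 2, 1, 1, 4))
})

test_that("manifest constructor enforces its invariants", {
  expect_error(cpg_manifest(c("a", "a"), 1:2, c("island", "island")),
               "duplicated probe_id")
  expect_error(cpg_manifest(c("a", "b"), c(1, 3), c("island", "island")),
               "consecutive")
  expect_error(cpg_manifest("a", 1, "promoter"), "unknown region")
  # order is normalised to order_index
  m <- cpg_manifest(c("b", "a"), c(2, 1), c("island", "north_shore"))
  expect_equal(m$probe_id, c("a", "b"))
})

test_that("beta matrix TSV round-trips losslessly, shuffled or not", {
  man <- toy_manifest()
  x <- toy_beta_matrix()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_beta_matrix(x, tsv)
  y <- read_beta_matrix(tsv, man)
  expect_identical(rownames(y), rownames(x))
  expect_identical(colnames(y), colnames(x))
  expect_equal(unclass(y), unclass(x), tolerance = 1e-12)

  # shuffling the rows of the file yields the identical matrix
  lines <- readLines(tsv)
  shuf <- c(lines[1], lines[c(4, 2, 6, 3, 5)])
  tsv2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(shuf, tsv2)
  z <- read_beta_matrix(tsv2, man)
  expect_equal(unclass(z), unclass(y), tolerance = 1e-12)
})

test_that("beta matrix reader rejects bad cells and unknown probes", {
  man <- toy_manifest()
  x <- toy_beta_matrix()
  bad <- unclass(x)
  bad[2, 3] <- 1.2
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(probe_id = rownames(bad), bad,
                         check.names = FALSE),
              tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_beta_matrix(tsv, man), "cg000002.*c3:birth")

  renamed <- unclass(x)
  rownames(renamed)[1] <- "cg_unknown"
  write.table(data.frame(probe_id = rownames(renamed), renamed,
                         check.names = FALSE),
              tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_beta_matrix(tsv, man), "unknown probe")
})

test_that("missing beta values are preserved as missing", {
  man <- toy_manifest()
  x <- unclass(toy_beta_matrix())
  x[1, 2] <- NA
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_beta_matrix(meth_matrix(x, "beta"), tsv)
  y <- read_beta_matrix(tsv, man)
  expect_true(is.na(unclass(y)[1, 2]))
  expect_equal(sum(is.na(unclass(y))), 1)
})

test_that("sample sheet validation catches duplicates and bad enums", {
  csv <- withr::local_tempfile(fileext = ".csv")
  write.csv(toy_sheet(), csv, row.names = FALSE)
  sh <- read_sample_sheet(csv)
  expect_equal(nrow(sh), 3)
  expect_true(is.na(sh$birthweight_kg[2]))
  expect_equal(sh$sample_visit_id, c("c1:birth", "c2:birth", "c3:birth"))

  dup <- rbind(toy_sheet(), toy_sheet()[1, ])
  write.csv(dup, csv, row.names = FALSE)
  expect_error(read_sample_sheet(csv), "duplicated")

  bad <- toy_sheet(); bad$sex[1] <- "M"
  write.csv(bad, csv, row.names = FALSE)
  expect_error(read_sample_sheet(csv), "sex")

  bad <- toy_sheet(); bad$timepoint[1] <- "cord"
  write.csv(bad, csv, row.names = FALSE)
  expect_error(read_sample_sheet(csv), "timepoint")
})

test_that("cell proportions must form a simplex when present", {
  sh <- toy_sheet()
  sh$cell_lymph <- c(0.4, 0.5, 0.6)
  sh$cell_gran <- c(0.6, 0.5, 0.3)  # last row sums to 0.9
  csv <- withr::local_tempfile(fileext = ".csv")
  write.csv(sh, csv, row.names = FALSE)
  expect_error(read_sample_sheet(csv), "sum to 1")
  sh$cell_gran[3] <- 0.4
  write.csv(sh, csv, row.names = FALSE)
  expect_equal(nrow(read_sample_sheet(csv)), 3)
})

test_that("weight-gain rate is (gain)/(exact age), kg per month", {
  expect_equal(derive_weight_gain_rate(7.7, 3.5, 6.0), 0.70)
  expect_equal(derive_weight_gain_rate(3.5, 3.5, 6.0), 0.0)
  # hand computation: (8.0 - 3.46) / 6.2
  expect_equal(derive_weight_gain_rate(8.0, 3.46, 6.2),
               0.732258064516129, tolerance = 1e-12)
  expect_error(derive_weight_gain_rate(8, 3.5, 0), "positive")
})
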