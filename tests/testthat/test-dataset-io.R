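test_that("SOFT parsing maps samples to times via subsets and preserves row order", {
  f <- write_soft_fixture(tempfile(fileext = ".soft"))
  ds <- read_soft_gds(f)
  expect_equal(ds$gene_ids, c("p1", "p2", "p3"))
  expect_equal(ds$annotations, c("geneA", "geneB", "geneC"))
  expect_equal(ds$conditions, "all")
  expect_equal(ds$time_points$all, c(0, 1))
  expect_equal(unname(ds$values$all), matrix(c(1.5, 3, 5, 2.5, 4, 6), ncol = 2))
  expect_equal(sum(is.na(ds$values$all)), 0)
})

test_that("SOFT 'null' cells become missing, others untouched", {
  f <- write_soft_fixture(tempfile(fileext = ".soft"), null_cell = TRUE)
  ds <- read_soft_gds(f)
  expect_true(is.na(ds$values$all["p1", 2]))
  expect_equal(sum(is.na(ds$values$all)), 1)
  expect_equal(unname(ds$values$all["p1", 1]), 1.5)
})

test_that("SOFT sample without subset coverage is a mapping error naming it", {
  f <- write_soft_fixture(tempfile(fileext = ".soft"), orphan_sample = TRUE)
  expect_error(read_soft_gds(f), "GSM2")
  expect_error(read_soft_gds(textConnection("no table here") |>
    (\(con) { p <- tempfile(); writeLines(readLines(con), p); p })()),
    "format error")
})

test_that("native CSV reorders out-of-order time columns by time value", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("gene_id,c1|2|1,c1|0|1,c1|1|1",
               "g1,30,10,20", "g2,3,1,2"), p)
  ds <- read_csv_native(p)
  expect_equal(ds$time_points$c1, c(0, 1, 2))
  expect_equal(unname(ds$values$c1["g1", ]), c(10, 20, 30))
  expect_equal(unname(ds$values$c1["g2", ]), c(1, 2, 3))
})

test_that("replicate columns collapse to the mean, ignoring missing", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("gene_id,c1|0|1,c1|0|2,c1|1|1,c1|1|2",
               "g1,2,4,2,NA", "g2,NA,NA,5,7"), p)
  ds <- read_csv_native(p)
  expect_equal(unname(ds$values$c1["g1", ]), c(3, 2))
  expect_true(is.na(ds$values$c1["g2", 1]))
  expect_equal(unname(ds$values$c1["g2", 2]), 6)
  expect_equal(ds$replicate_sets$c1[[1]], c("c1|0|1", "c1|0|2"))
})

test_that("replicate collapsing is invariant to replicate column order", {
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  writeLines(c("gene_id,c1|0|1,c1|0|2,c1|1|1", "g1,2,5,1"), p1)
  writeLines(c("gene_id,c1|0|2,c1|0|1,c1|1|1", "g1,5,2,1"), p2)
  expect_equal(read_csv_native(p1)$values, read_csv_native(p2)$values)
})

test_that("CSV import rejects duplicate gene ids and bad cells with location", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("gene_id,c1|0|1,c1|1|1", "g1,1,2", "g1,3,4"), p)
  expect_error(read_csv_native(p), "duplicate gene ids.*g1")
  writeLines(c("gene_id,c1|0|1,c1|1|1", "g1,1,oops"), p)
  expect_error(read_csv_native(p), "oops")
})

test_that("write/read round trip is value-exact including the missing mask", {
  set.seed(5)
  V1 <- matrix(rnorm(300), nrow = 50); V1[sample(300, 20)] <- NA
  V2 <- matrix(rnorm(300), nrow = 50); V2[sample(300, 15)] <- NA
  ds <- expression_dataset("rt", paste0("g", 1:50), c("a", "b"),
                           list(a = c(0, 1, 2.5, 4, 8, 16), b = 1:6),
                           list(a = V1, b = V2))
  p <- tempfile(fileext = ".csv")
  write_csv_native(ds, p)
  back <- read_csv_native(p, dataset_id = "rt")
  expect_identical(back$gene_ids, ds$gene_ids)
  expect_identical(back$conditions, ds$conditions)
  expect_equal(back$time_points, ds$time_points)
  expect_identical(unname(back$values$a), unname(V1))
  expect_identical(unname(back$values$b), unname(V2))
})

test_that("empty gene list round-trips to a header-only file", {
  ds <- expression_dataset("empty", character(), "c1", list(c1 = c(0, 1)),
                           list(c1 = matrix(numeric(), nrow = 0, ncol = 2)))
  p <- tempfile(fileext = ".csv")
  write_csv_native(ds, p)
  expect_equal(length(readLines(p)), 1L)
  expect_equal(length(read_csv_native(p)$gene_ids), 0L)
})

test_that("SOFT and CSV readers agree on equivalent fixtures", {
  f <- write_soft_fixture(tempfile(fileext = ".soft"))
  soft <- read_soft_gds(f)
  p <- tempfile(fileext = ".csv")
  writeLines(c("gene_id,annotation,all|0|1,all|1|1",
               "p1,geneA,1.5,2.5", "p2,geneB,3,4", "p3,geneC,5,6"), p)
  csv <- read_csv_native(p)
  expect_identical(unname(soft$values$all), unname(csv$values$all))
  expect_identical(soft$gene_ids, csv$gene_ids)
  expect_equal(soft$time_points, csv$time_points)
})

test_that("validate_dataset reports counts and invariant violations", {
  ds <- toy_dataset(matrix(1:6, nrow = 2), times = c(0, 1, 2))
  rep <- validate_dataset(ds)
  expect_true(rep$pass)
  expect_equal(rep$n_genes, 2L)
  expect_equal(unname(rep$n_time_points["c1"]), 3L)
  bad <- unclass(ds)
  bad$time_points$c1 <- c(0, 2, 1)
  expect_false(validate_dataset(bad)$pass)
  expect_match(validate_dataset(bad)$failures, "c1")
})

test_that("the 17-point developmental-stage fixture validates with 17 time points", {
  spec <- paper_shapes()$mammary17
  spec$n_genes <- 400L  # structural check at reduced scale
  fx <- generate_fixture(spec)
  rep <- validate_dataset(fx$dataset)
  expect_true(rep$pass)
  expect_equal(unname(rep$n_time_points), 17L)
  expect_equal(ds_labels <- fx$dataset$time_labels$mammary[1:3],
               c("V10", "V12", "P1"))
})

test_that("MAGE-TAB loading refuses with a clear message", {
  expect_error(read_mage_tab(tempfile()), "format not supported")
})
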