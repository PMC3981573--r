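# fixture builders and independent oracles shared across the suite

toy_dataset <- function(values, times = seq_len(ncol(values)) - 1,
                        gene_ids = paste0("g", seq_len(nrow(values))),
                        condition = "c1", dataset_id = "toy") {
  expression_dataset(dataset_id, gene_ids, condition,
                     stats::setNames(list(as.numeric(times)), condition),
                     stats::setNames(list(values), condition))
}

random_dataset <- function(n_genes, times, seed, missing_rate = 0,
                           condition = "c1", dataset_id = "rand") {
  set.seed(seed)
  V <- matrix(rnorm(n_genes * length(times)), nrow = n_genes)
  if (missing_rate > 0) {
    V[sample(length(V), round(missing_rate * length(V)))] <- NA
  }
  expression_dataset(dataset_id, paste0("g", seq_len(n_genes)), condition,
                     stats::setNames(list(as.numeric(times)), condition),
                     stats::setNames(list(V), condition))
}

# independent interval-summary oracle: naive recomputation from the raw
# value table using stats::approx (a different code path from the layout)
oracle_summary <- function(values, times, s, e, mode = "difference") {
  v0 <- stats::approx(times, values, xout = s)$y
  vn <- stats::approx(times, values, xout = e)$y
  inner <- values[times > s & times < e]
  y <- mean(c(v0, inner, vn))
  x <- if (mode == "difference") vn - v0 else vn / v0
  c(x = x, y = y)
}

# minimal GDS SOFT fixture text
write_soft_fixture <- function(path, null_cell = FALSE, orphan_sample = FALSE) {
  samples <- c("GSM1", "GSM2")
  header <- paste(c("ID_REF", "IDENTIFIER", samples), collapse = "\t")
  rows <- c(paste("p1", "geneA", "1.5", if (null_cell) "null" else "2.5",
                  sep = "\t"),
            paste("p2", "geneB", "3", "4", sep = "\t"),
            paste("p3", "geneC", "5", "6", sep = "\t"))
  subset2 <- if (orphan_sample) character() else c(
    "^SUBSET = GDS_toy_2",
    "!subset_description = 1 hour",
    "!subset_sample_id = GSM2",
    "!subset_type = time")
  writeLines(c(
    "^DATASET = GDS_toy",
    "!dataset_table_begin", header, rows, "!dataset_table_end",
    "^SUBSET = GDS_toy_1",
    "!subset_description = 0 hour",
    "!subset_sample_id = GSM1",
    "!subset_type = time",
    subset2), path)
  path
}

swing_spec <- function(n_genes = 500, seed = 11, missing_rate = 0) {
  fixture_spec(n_genes = n_genes, times = 0:9,
               planted = list(list(name = "swing", n = 30, interval = c(3, 5),
                                   shape = "rise_fall", effect = 6)),
               missing_rate = missing_rate, seed = seed)
}
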