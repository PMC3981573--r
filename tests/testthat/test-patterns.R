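three_gene_frame_ds <- function() {
  # genes at (x, y) = (-1, 0), (2, 1), (5, 3) over the full interval [0, 1]
  V <- rbind(c(0.5, -0.5), c(0, 2), c(0.5, 5.5))
  toy_dataset(V, times = c(0, 1))
}

test_that("box queries select by closed containment of frame summaries", {
  ds <- three_gene_frame_ds()
  expect_equal(evaluate_box(ds, box_query("c1", 0, 1, x_min = 1, x_max = 3)),
               "g2")
  expect_setequal(
    evaluate_box(ds, box_query("c1", 0, 1, x_min = -10, x_max = 10)),
    c("g1", "g2", "g3"))
  # closed bounds include genes sitting exactly on an edge
  expect_equal(evaluate_box(ds, box_query("c1", 0, 1, x_min = 2, x_max = 3)),
               "g2")
})

test_that("unsnapped query intervals are refused", {
  ds <- three_gene_frame_ds()
  expect_error(evaluate_box(ds, box_query("c1", 0, 0.7, x_min = 0)),
               "snap before querying")
})

test_that("frame-excluded genes never match a box", {
  V <- matrix(c(10, 10, NA, 10), nrow = 2, byrow = TRUE)
  ds <- toy_dataset(V, times = 0:1)
  got <- evaluate_box(ds, box_query("c1", 0, 1, y_min = -100))
  expect_equal(got, "g1")
})

test_that("Boolean algebra: contradiction empty, tautology all, oracle agreement", {
  ds <- random_dataset(60, 0:5, seed = 50)
  A <- box_query("c1", 0, 3, x_min = 0)
  expect_equal(evaluate_expression(ds, q_and(A, q_not(A))), character())
  expect_setequal(evaluate_expression(ds, q_or(A, q_not(A))), ds$gene_ids)
  # brute-force oracle on random boxes
  set.seed(51)
  for (i in 1:10) {
    tt <- ds$time_points$c1
    ab <- sort(sample(tt, 2))
    b <- box_query("c1", ab[1], ab[2],
                   x_min = runif(1, -2, 0), y_max = runif(1, 0, 2))
    fr <- frame_at(ds, interval_selection("c1", ab[1], ab[2], TRUE))
    want <- with(fr$summaries, gene_id[x >= b$x_min & y <= b$y_max])
    expect_setequal(evaluate_box(ds, b), want)
  }
})

test_that("De Morgan identities hold on randomized expressions", {
  ds <- random_dataset(80, 0:6, seed = 52)
  set.seed(53)
  tt <- ds$time_points$c1
  for (i in 1:8) {
    ab <- sort(sample(tt, 2)); cd <- sort(sample(tt, 2))
    A <- box_query("c1", ab[1], ab[2], x_min = rnorm(1))
    B <- box_query("c1", cd[1], cd[2], y_max = rnorm(1))
    lhs <- evaluate_expression(ds, q_not(q_or(A, B)))
    rhs <- evaluate_expression(ds, q_and(q_not(A), q_not(B)))
    expect_identical(lhs, rhs)
    lhs2 <- evaluate_expression(ds, q_not(q_and(A, B)))
    rhs2 <- evaluate_expression(ds, q_or(q_not(A), q_not(B)))
    expect_identical(lhs2, rhs2)
  }
})

test_that("query monotonicity: enlarging a box never loses genes", {
  ds <- random_dataset(60, 0:5, seed = 54)
  small <- box_query("c1", 0, 5, x_min = -0.5, x_max = 0.5)
  big <- box_query("c1", 0, 5, x_min = -1.5, x_max = 1.5)
  expect_true(all(evaluate_box(ds, small) %in% evaluate_box(ds, big)))
})

test_that("edge rounding uses the span/100 1-2-5 grid and is idempotent", {
  expect_equal(nice_step(10), 0.1)
  expect_equal(nice_step(7), 0.05)
  expect_equal(nice_step(100), 1)
  q <- box_query("c1", 0, 1, x_min = 1.2345)
  r <- round_edges(q, x_range = c(0, 10), y_range = c(0, 10))
  expect_equal(r$x_min, 1.2)
  # fixed point: a value already on the grid is unchanged
  expect_equal(round_edges(r, c(0, 10), c(0, 10))$x_min, 1.2)
  q2 <- box_query("c1", 0, 1, x_min = 0.501, x_max = 0.549)
  expect_error(round_edges(q2, c(0, 10), c(0, 10)), "degenerate")
})

test_that("simplification drops superfluous edges and is idempotent", {
  ext <- list(x = c(-3, 3), y = c(-2, 2))
  q <- box_query("c1", 0, 1, y_min = 0.5, y_max = 10)
  s <- simplify_query(q, ext)
  expect_equal(s$y_min, 0.5)
  expect_null(s$y_max)
  expect_identical(simplify_query(s, ext), s)
  inside <- box_query("c1", 0, 1, x_min = -1, x_max = 1)
  expect_identical(simplify_query(inside, ext), inside)
  everything <- box_query("c1", 0, 1, x_min = -5, x_max = 5)
  expect_error(simplify_query(everything, ext), "selects everything")
})

test_that("patterns round-trip through JSON canonically", {
  ds <- random_dataset(40, 0:4, seed = 55)
  expr <- q_and(box_query("c1", 0, 2, x_min = 0.5),
                q_or(box_query("c1", 2, 4, y_max = 0),
                     q_not(box_query("c1", 0, 4, x_max = 1))))
  genes <- evaluate_expression(ds, expr)
  p <- pattern("p1", ds, expr, result_genes = genes,
               annotations = "rise then fall", created = "2026-01-01T00:00:00Z")
  f <- tempfile(fileext = ".pattern.json")
  save_pattern(p, f)
  back <- load_pattern(f)
  expect_identical(canonical_expression(back$expression),
                   canonical_expression(p$expression))
  expect_identical(back$result_genes, genes)
  expect_identical(back$transforms, p$transforms)
  expect_identical(back$created, p$created)
})

test_that("canonical serialization is order-invariant for AND/OR operands", {
  A <- box_query("c1", 0, 1, x_min = 1)
  B <- box_query("c1", 0, 1, y_max = 2)
  expect_identical(canonical_expression(q_and(A, B)),
                   canonical_expression(q_and(B, A)))
  expect_identical(canonical_expression(q_or(A, q_or(B, A))),
                   canonical_expression(q_or(q_or(A, B), A)))
})

test_that("dataset-id mismatch warns on load and blocks evaluation", {
  ds <- random_dataset(10, 0:2, seed = 56)
  other <- random_dataset(10, 0:2, seed = 56, dataset_id = "other")
  p <- pattern("p1", ds, box_query("c1", 0, 2, x_min = 0))
  f <- tempfile(fileext = ".json")
  save_pattern(p, f)
  expect_warning(load_pattern(f, dataset = other), "mismatch")
  expect_error(evaluate_pattern(other, p), "mismatch")
  expect_silent(evaluate_pattern(other, p, override = TRUE))
})

test_that("unknown pattern file versions are a format error", {
  f <- tempfile(fileext = ".json")
  writeLines('{"format_version": 99, "expression": "x"}', f)
  expect_error(load_pattern(f), "format error")
})

test_that("re-evaluating a loaded pattern on the regenerated fixture reproduces results", {
  fx <- generate_fixture(swing_spec(seed = 60))
  expr <- q_and(box_query("c1", 3, 4, x_min = 0.6),
                box_query("c1", 4, 5, x_max = -0.6))
  genes <- evaluate_expression(fx$dataset, expr)
  p <- pattern("swing", fx$dataset, expr, result_genes = genes,
               created = "2026-01-01T00:00:00Z")
  f <- tempfile(fileext = ".json")
  save_pattern(p, f)
  fx2 <- generate_fixture(swing_spec(seed = 60))
  back <- load_pattern(f, dataset = fx2$dataset)
  expect_identical(evaluate_pattern(fx2$dataset, back), back$result_genes)
})

test_that("refinement swaps one leaf and invalidates cached results", {
  ds <- random_dataset(20, 0:3, seed = 57)
  p <- pattern("p", ds, q_and(box_query("c1", 0, 1, x_min = 0),
                              box_query("c1", 1, 3, y_min = 0)),
               result_genes = c("g1"))
  p2 <- refine_pattern(p, 2, box_query("c1", 1, 3, y_max = 0))
  expect_null(p2$result_genes)
  expect_match(canonical_expression(p2$expression), "y_max=0")
  expect_error(refine_pattern(p, 5, box_query("c1", 0, 1, x_min = 0)),
               "out of range")
})

test_that("gene export writes one id per line", {
  p <- pattern("p", "ds", box_query("c1", 0, 1, x_min = 0),
               result_genes = c("gA", "gB"))
  f <- tempfile()
  export_genes(p, f)
  expect_equal(readLines(f), c("gA", "gB"))
  p$result_genes <- NULL
  expect_error(export_genes(p, f), "evaluate")
})
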