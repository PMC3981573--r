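test_that("interval summary applies the difference/mean formulas", {
  ds <- toy_dataset(matrix(c(2, 4, 6), nrow = 1), times = 0:2)
  s <- summarize_interval(ds, "g1", interval_selection("c1", 0, 2, TRUE))
  expect_equal(s$x, 4)
  expect_equal(s$y, 4)
  expect_equal(s$marker_class, "measured")
})

test_that("a constant series maps to x = 0 (difference) or 1 (fold), y = c", {
  ds <- toy_dataset(matrix(rep(3.5, 5), nrow = 1), times = 0:4)
  sel <- interval_selection("c1", 1, 3, TRUE)
  d <- summarize_interval(ds, "g1", sel, "difference")
  f <- summarize_interval(ds, "g1", sel, "fold_change")
  expect_equal(d$x, 0); expect_equal(d$y, 3.5)
  expect_equal(f$x, 1); expect_equal(f$y, 3.5)
})

test_that("snapped-interval layout matches the brute-force oracle to 1e-12", {
  ds <- random_dataset(30, times = sort(runif(8, 0, 20)), seed = 21)
  tt <- ds$time_points$c1
  for (a in 1:(length(tt) - 1)) for (b in (a + 1):length(tt)) {
    fr <- frame_at(ds, interval_selection("c1", tt[a], tt[b], TRUE))
    for (i in c(1, 15, 30)) {
      want <- oracle_summary(ds$values$c1[i, ], tt, tt[a], tt[b])
      row <- fr$summaries[fr$summaries$gene_id == paste0("g", i), ]
      expect_equal(row$x, unname(want["x"]), tolerance = 1e-12)
      expect_equal(row$y, unname(want["y"]), tolerance = 1e-12)
    }
  }
})

test_that("fold-change mode is vn/v0 and rejects zero or sign-changing v0", {
  ds <- toy_dataset(matrix(c(2, -1, 0, 4, 2, 5, 8, 3, 6), nrow = 3),
                    times = 0:2)
  sel <- interval_selection("c1", 0, 2, TRUE)
  expect_equal(summarize_interval(ds, "g1", sel, "fold_change")$x, 4)
  expect_error(summarize_interval(ds, "g2", sel, "fold_change"), "domain error")
  expect_error(summarize_interval(ds, "g3", sel, "fold_change"), "domain error")
})

test_that("zero-duration x is the midpoint of flanking interval differences", {
  ds <- toy_dataset(matrix(c(1, 3, 2), nrow = 1), times = 0:2)
  # d = [2, -1]
  s1 <- summarize_zero_duration(ds, "g1", 1)
  expect_equal(s1$x, 0.5)
  expect_equal(s1$y, 3)
  expect_equal(summarize_zero_duration(ds, "g1", 0)$x, 2)
  expect_equal(summarize_zero_duration(ds, "g1", 2)$x, -1)
})

test_that("zero-duration x interpolates linearly between grid points", {
  ds <- toy_dataset(matrix(c(1, 3, 2), nrow = 1), times = 0:2)
  x_at <- function(t) summarize_zero_duration(ds, "g1", t)$x
  expect_equal(x_at(0.5), (x_at(0) + x_at(1)) / 2, tolerance = 1e-12)
  expect_equal(x_at(1.25), 0.75 * x_at(1) + 0.25 * x_at(2), tolerance = 1e-12)
})

test_that("zero-duration y equals value_at(t) exactly", {
  ds <- random_dataset(10, 0:6, seed = 30, missing_rate = 0.1)
  fr <- frame_at(ds, interval_selection("c1", 2.3, 2.3))
  for (g in fr$summaries$gene_id) {
    expect_equal(fr$summaries$y[fr$summaries$gene_id == g],
                 value_at(ds, g, "c1", 2.3)$value)
  }
})

test_that("zero-duration x tracks the slope sign on monotone series", {
  set.seed(31)
  for (rep in 1:5) {
    v <- cumsum(runif(7, 0.1, 1))
    ds <- toy_dataset(matrix(v, nrow = 1), times = 0:6)
    for (t in seq(0, 6, by = 0.5)) {
      expect_gt(summarize_zero_duration(ds, "g1", t)$x, 0)
    }
  }
})

test_that("fold-change zero-duration exponentiates from ratios", {
  ds <- toy_dataset(matrix(c(1, 2, 8), nrow = 1), times = 0:2)
  # ratios 2 and 4; geometric midpoint at t=1 is sqrt(8)
  expect_equal(summarize_zero_duration(ds, "g1", 1, "fold_change")$x,
               sqrt(8), tolerance = 1e-12)
  expect_equal(summarize_zero_duration(ds, "g1", 0, "fold_change")$x, 2)
})

test_that("snapping picks the nearest grid time, ties to the earlier point", {
  ds <- toy_dataset(matrix(1:3, nrow = 1), times = 0:2)
  s <- snap(interval_selection("c1", 0.9, 2.0), ds)
  expect_equal(c(s$start, s$end), c(1, 2))
  expect_true(s$snapped)
  expect_equal(snap(interval_selection("c1", 0.5, 2), ds)$start, 0)
  s2 <- snap(s, ds)
  expect_equal(c(s2$start, s2$end), c(s$start, s$end))
})

test_that("frames partition genes into placed and excluded", {
  V <- matrix(c(1, 2, 3, NA, 2, 3, 1, 2, NA), nrow = 3, byrow = TRUE)
  ds <- toy_dataset(V, times = 0:2)
  fr <- frame_at(ds, interval_selection("c1", 0, 2, TRUE))
  expect_setequal(c(fr$summaries$gene_id, fr$excluded), ds$gene_ids)
  expect_setequal(fr$excluded, c("g2", "g3"))
  fr2 <- frame_at(ds, interval_selection("c1", 1, 2, TRUE))
  expect_setequal(fr2$excluded, "g3")
  expect_error(frame_at(ds, interval_selection("nope", 0, 1)), "lookup error")
})

test_that("marker classes follow the endpoint/interior interpolation rule", {
  V <- matrix(c(1, 2, 3, 4,
                1, NA, 3, 4,
                1, 2, 3, 4), nrow = 3, byrow = TRUE)
  V[3, 4] <- NA  # trailing gap for g3
  ds <- toy_dataset(V, times = 0:3)
  fr <- frame_at(ds, interval_selection("c1", 0, 3, TRUE))
  s <- fr$summaries
  expect_equal(s$marker_class[s$gene_id == "g1"], "measured")
  expect_equal(s$marker_class[s$gene_id == "g2"], "y_interpolated")
  # interval ending on a filled cell -> endpoint interpolated
  V2 <- matrix(c(1, NA, 3), nrow = 1)
  ds2 <- toy_dataset(V2, times = 0:2)
  fr2 <- frame_at(ds2, interval_selection("c1", 0, 1, TRUE))
  expect_equal(fr2$summaries$marker_class, "xy_interpolated")
})

test_that("difference-mode x is translation-equivariant", {
  ds <- random_dataset(20, 0:8, seed = 40)
  shifted <- ds
  shifted$values$c1 <- ds$values$c1 + 7
  sel <- interval_selection("c1", 2, 6, TRUE)
  a <- frame_at(ds, sel)$summaries
  b <- frame_at(shifted, sel)$summaries
  expect_equal(b$x, a$x, tolerance = 1e-12)
  expect_equal(b$y, a$y + 7, tolerance = 1e-12)
})

test_that("frame coordinates move continuously between grid crossings", {
  ds <- random_dataset(15, 0:9, seed = 41)
  eps <- 1e-6
  f1 <- frame_at(ds, interval_selection("c1", 2.3, 5.6))
  f2 <- frame_at(ds, interval_selection("c1", 2.3 + eps, 5.6 + eps))
  expect_equal(f2$summaries$x, f1$summaries$x, tolerance = 1e-4)
  expect_equal(f2$summaries$y, f1$summaries$y, tolerance = 1e-4)
})

test_that("animation sweeps the span evenly, ending on grid extremes", {
  ds <- toy_dataset(matrix(c(0, 1, 0), nrow = 1), times = 0:2)
  frames <- animate(ds, "c1", "zero_duration", steps = 3)
  at <- vapply(frames, function(f) f$selection$start, numeric(1))
  expect_equal(at, c(0, 1, 2))
  expect_error(animate(ds, "c1", "fixed_window", steps = 3, width = 5),
               "parameter error")
  expect_error(animate(ds, "c1", steps = 1), "parameter error")
})

test_that("a single-peak gene swings right before the peak, left after", {
  ds <- toy_dataset(matrix(c(0, 1, 0), nrow = 1), times = 0:2)
  frames <- animate(ds, "c1", "zero_duration", steps = 9)
  xs <- vapply(frames, function(f) f$summaries$x, numeric(1))
  ts <- vapply(frames, function(f) f$selection$start, numeric(1))
  expect_true(all(xs[ts < 1] > 0))
  expect_true(all(xs[ts > 1] < 0))
})

test_that("a sampled single-peak profile sweeps an anticlockwise trajectory", {
  times <- 0:11
  v <- sin(pi * times / 11)^2  # nonnegative single peak
  ds <- toy_dataset(matrix(v, nrow = 1), times = times)
  frames <- animate(ds, "c1", "fixed_window", steps = 40, width = 3)
  xy <- t(vapply(frames, function(f)
    c(f$summaries$x, f$summaries$y), numeric(2)))
  expect_gt(polygon_signed_area(xy), 0)
})

test_that("frame CSV export covers all genes in dataset order", {
  V <- matrix(c(1, 2, 3, NA, 2, 3), nrow = 2, byrow = TRUE)
  ds <- toy_dataset(V, times = 0:2)
  fr <- frame_at(ds, interval_selection("c1", 0, 2, TRUE))
  p <- tempfile(fileext = ".csv")
  write_frame_csv(fr, p)
  out <- read.csv(p)
  expect_equal(out$gene_id, c("g1", "g2"))
  expect_equal(out$excluded, c(FALSE, TRUE))
  expect_true(is.na(out$x[2]))
})
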