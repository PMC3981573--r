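#' Interval selection on one condition's time axis
#'
#' The selection drives the scatter-plot: all genes are summarized over the
#' window `[start, end]` of the chosen condition. A zero-duration selection
#' (`start == end`) is legal and uses the interpolated change-in-value
#' layout. `snapped` records whether both endpoints coincide with measured
#' grid times; queries are only evaluable on snapped selections, so that
#' results never depend on display interpolation.
#'
#' @param condition Condition label.
#' @param start,end Numeric times, `start <= end`.
#' @param snapped Logical; set by [snap()].
#' @return An `IntervalSelection`.
#' @export
interval_selection <- function(condition, start, end, snapped = FALSE) {
  if (!(is.numeric(start) && is.numeric(end)) || is.na(start) || is.na(end)) {
    stop("start and end must be numeric")
  }
  if (start > end) stop("selection start must not exceed end")
  structure(list(condition = as.character(condition), start = as.numeric(start),
                 end = as.numeric(end), snapped = isTRUE(snapped)),
            class = "IntervalSelection")
}

#' Snap a selection's endpoints to the nearest measured time points
#'
#' Each endpoint moves to the nearest grid time of its condition, ties
#' resolving to the earlier time point. Snapping is what makes query results
#' depend on measured data only.
#'
#' @param selection An [interval_selection()].
#' @param dataset The dataset supplying the condition's time grid.
#' @return The snapped selection (`snapped = TRUE`). Idempotent.
#' @export
snap <- function(selection, dataset) {
  tt <- dataset$time_points[[selection$condition]]
  if (is.null(tt)) stop("unknown condition: ", selection$condition)
  near <- function(t) tt[which.min(abs(tt - t))]  # which.min: tie -> earlier
  s <- near(selection$start); e <- near(selection$end)
  interval_selection(selection$condition, min(s, e), max(s, e), snapped = TRUE)
}

# endpoint evaluation for all genes at once: value and whether the value
# rests on missing-data interpolation (filled grid cells)
eval_all_at <- function(V, M, tt, t) {
  hit <- which(abs(tt - t) < 1e-12)
  if (length(hit)) {
    k <- hit[1]
    return(list(value = V[, k], interp = M[, k], cols = k))
  }
  j <- findInterval(t, tt)
  j <- min(max(j, 1L), length(tt) - 1L)
  w <- (t - tt[j]) / (tt[j + 1] - tt[j])
  list(value = V[, j] + (V[, j + 1] - V[, j]) * w,
       interp = M[, j] | M[, j + 1], cols = c(j, j + 1L))
}

# mean of columns of a possibly 0-column matrix bound with endpoint vectors
row_mean_with <- function(v0, inner, vn) {
  rowMeans(cbind(v0, inner, vn))
}

#' Compute a full scatter-plot frame for a selection
#'
#' For a proper interval (duration > 0) each gene maps to
#' `x` = change in activity (`v_n - v_0` in difference mode, `v_n / v_0` in
#' fold-change mode) and `y` = mean activity: the arithmetic mean of the
#' endpoint values and all grid values strictly inside the interval. For a
#' zero-duration selection `y` is the series value at `t` and `x` is
#' interpolated from the flanking proper grid intervals (midpoint of the two
#' one-step differences at a grid point, endpoint intervals at the grid
#' extremes, linear between grid points; fold mode does the same on log
#' ratios and exponentiates). Genes whose covered span does not contain the
#' window are listed in `excluded` rather than positioned.
#'
#' Marker classes record missing-data interpolation: `xy_interpolated` when
#' an endpoint value rests on a filled cell, `y_interpolated` when only
#' interior values do, `measured` otherwise.
#'
#' @param dataset An `ExpressionDataset`.
#' @param selection An [interval_selection()].
#' @param axis_mode `"difference"` or `"fold_change"`.
#' @return A `Frame`: list with `selection`, `summaries` (data.frame
#'   `gene_id, x, y, marker_class` in dataset gene order), `excluded`
#'   (gene ids) and `excluded_reason`.
#' @export
frame_at <- function(dataset, selection, axis_mode = c("difference", "fold_change")) {
  axis_mode <- match.arg(axis_mode)
  cn <- selection$condition
  if (!cn %in% dataset$conditions) stop("lookup error: unknown condition: ", cn)
  dataset <- fill_missing(dataset)
  tt <- dataset$time_points[[cn]]
  V <- dataset$values[[cn]]
  M <- dataset$interpolated[[cn]]
  n <- nrow(V)
  sp <- covered_span(V)
  s <- selection$start; e <- selection$end
  eps <- 1e-12
  covered <- !is.na(sp[, 1]) & tt[pmax(sp[, 1], 1L)] <= s + eps &
    tt[pmax(sp[, 2], 1L)] >= e - eps
  covered[is.na(covered)] <- FALSE
  reason <- rep(NA_character_, n)
  reason[!covered] <- "uncovered"

  x <- rep(NA_real_, n); y <- rep(NA_real_, n)
  end_interp <- rep(FALSE, n); int_interp <- rep(FALSE, n)

  if (e - s > eps) {
    a0 <- eval_all_at(V, M, tt, s)
    a1 <- eval_all_at(V, M, tt, e)
    inner_cols <- which(tt > s + eps & tt < e - eps)
    y <- row_mean_with(a0$value, V[, inner_cols, drop = FALSE], a1$value)
    end_interp <- a0$interp | a1$interp
    int_interp <- rowSums(M[, inner_cols, drop = FALSE]) > 0L
    if (axis_mode == "difference") {
      x <- a1$value - a0$value
    } else {
      invalid <- covered & (is.na(a0$value) | a0$value == 0 |
                              a0$value * a1$value < 0)
      x <- a1$value / a0$value
      covered[invalid] <- FALSE
      reason[invalid] <- "fold_change_domain"
    }
  } else {
    # zero-duration layout
    covered2 <- covered & (sp[, 2] - sp[, 1] >= 1L)
    reason[covered & !covered2] <- "uncovered"
    covered <- covered2
    at <- eval_all_at(V, M, tt, s)
    y <- at$value
    end_interp <- at$interp
    Tn <- length(tt)
    if (axis_mode == "difference") {
      D <- V[, -1L, drop = FALSE] - V[, -Tn, drop = FALSE]
    } else {
      R <- V[, -1L, drop = FALSE] / V[, -Tn, drop = FALSE]
      bad <- covered & rowSums(!is.na(R) & R <= 0) > 0L
      covered[bad] <- FALSE
      reason[bad] <- "fold_change_domain"
      D <- log(R)
    }
    xg <- function(k) {
      left <- if (k >= 2L) D[, k - 1L] else rep(NA_real_, n)
      right <- if (k <= Tn - 1L) D[, k] else rep(NA_real_, n)
      out <- rowMeans(cbind(left, right), na.rm = TRUE)
      out[is.nan(out)] <- NA_real_
      out
    }
    hit <- which(abs(tt - s) < 1e-12)
    if (length(hit)) {
      x <- xg(hit[1])
      flank_cols <- intersect(c(hit[1] - 1L, hit[1] + 1L), seq_len(Tn))
    } else {
      j <- min(max(findInterval(s, tt), 1L), Tn - 1L)
      w <- (s - tt[j]) / (tt[j + 1] - tt[j])
      x <- (1 - w) * xg(j) + w * xg(j + 1L)
      flank_cols <- intersect((j - 1L):(j + 2L), seq_len(Tn))
    }
    if (axis_mode == "fold_change") x <- exp(x)
    int_interp <- rowSums(M[, flank_cols, drop = FALSE]) > 0L
  }

  covered <- covered & !is.na(x) & !is.na(y)
  marker <- ifelse(end_interp, "xy_interpolated",
                   ifelse(int_interp, "y_interpolated", "measured"))
  inc <- which(covered)
  structure(list(
    selection = selection,
    summaries = data.frame(gene_id = dataset$gene_ids[inc], x = x[inc],
                           y = y[inc], marker_class = marker[inc],
                           stringsAsFactors = FALSE),
    excluded = dataset$gene_ids[!covered],
    excluded_reason = stats::setNames(reason[!covered],
                                      dataset$gene_ids[!covered]),
    gene_order = dataset$gene_ids
  ), class = "Frame")
}

#' @export
print.Frame <- function(x, ...) {
  cat("Frame [", x$selection$condition, " ", format(x$selection$start), "..",
      format(x$selection$end), if (x$selection$snapped) ", snapped", "]: ",
      nrow(x$summaries), " genes placed, ", length(x$excluded),
      " excluded\n", sep = "")
  invisible(x)
}

#' Summarize one gene over a proper interval
#'
#' Scalar companion of [frame_at()] for a selection with positive duration.
#' An uncovered gene yields `NULL` (an exclusion signal, not an error);
#' fold-change mode with a zero or sign-changing start value is a domain
#' error.
#'
#' @inheritParams frame_at
#' @param gene Gene identifier.
#' @return An `IntervalSummary` (list `gene, x, y, marker_class`) or `NULL`.
#' @export
summarize_interval <- function(dataset, gene, selection,
                               axis_mode = c("difference", "fold_change")) {
  axis_mode <- match.arg(axis_mode)
  if (selection$end - selection$start <= 1e-12) {
    stop("use summarize_zero_duration for zero-duration selections")
  }
  summary_from_frame(frame_at(dataset, selection, axis_mode), gene)
}

#' Summarize one gene at a zero-duration selection
#'
#' `y` is the series value at `t`; `x` is the interpolated change-in-value
#' built from the nearest proper grid intervals before and after `t`.
#'
#' @inheritParams summarize_interval
#' @param t Numeric time.
#' @param condition Condition label; defaults to the first condition.
#' @export
summarize_zero_duration <- function(dataset, gene, t,
                                    axis_mode = c("difference", "fold_change"),
                                    condition = dataset$conditions[1]) {
  axis_mode <- match.arg(axis_mode)
  cond <- condition
  sel <- interval_selection(cond, t, t)
  if (length(dataset$time_points[[cond]]) < 2L) {
    stop("layout error: condition has fewer than 2 time points")
  }
  summary_from_frame(frame_at(dataset, sel, axis_mode), gene)
}

summary_from_frame <- function(frame, gene) {
  i <- match(gene, frame$summaries$gene_id)
  if (is.na(i)) {
    if (identical(unname(frame$excluded_reason[gene]), "fold_change_domain")) {
      stop("domain error: fold change undefined for gene '", gene,
           "' (zero or sign-changing start value)")
    }
    if (gene %in% frame$excluded) return(NULL)
    stop("unknown gene: ", gene)
  }
  structure(list(gene = gene, x = frame$summaries$x[i], y = frame$summaries$y[i],
                 marker_class = frame$summaries$marker_class[i]),
            class = "IntervalSummary")
}

#' Sweep a selection across the time span, producing animation frames
#'
#' Frames are computed at `steps` evenly spaced selection positions (in time
#' value, not index) covering the full span of the condition; the first and
#' last frames coincide with the grid extremes. Intermediate positions are
#' unsnapped and use the same linear interpolation as [value_at()].
#'
#' @param dataset An `ExpressionDataset`.
#' @param condition Condition label.
#' @param mode `"zero_duration"` (a point selection sweeping the span) or
#'   `"fixed_window"` (a window of constant `width` whose start sweeps).
#' @param steps Number of frames, at least 2.
#' @param width Window width (time units) for `"fixed_window"`.
#' @param axis_mode `"difference"` or `"fold_change"`.
#' @return List of `Frame`s, in sweep order.
#' @export
animate <- function(dataset, condition, mode = c("zero_duration", "fixed_window"),
                    steps = 10L, width = 0,
                    axis_mode = c("difference", "fold_change")) {
  mode <- match.arg(mode)
  axis_mode <- match.arg(axis_mode)
  if (steps < 2L) stop("parameter error: steps must be at least 2")
  tt <- dataset$time_points[[condition]]
  if (is.null(tt)) stop("lookup error: unknown condition: ", condition)
  span <- max(tt) - min(tt)
  if (mode == "fixed_window") {
    if (width < 0 || width > span) {
      stop("parameter error: width must lie within the condition's time span")
    }
    starts <- seq(min(tt), max(tt) - width, length.out = steps)
    sels <- lapply(starts, function(s0)
      interval_selection(condition, s0, s0 + width))
  } else {
    at <- seq(min(tt), max(tt), length.out = steps)
    sels <- lapply(at, function(t0) interval_selection(condition, t0, t0))
  }
  lapply(sels, function(sel) frame_at(dataset, sel, axis_mode))
}

#' Export a frame as CSV
#'
#' One row per gene of the dataset, in dataset gene order, with columns
#' `gene_id, x, y, marker_class, excluded`; excluded genes carry empty
#' coordinates and `excluded = TRUE`.
#'
#' @param frame A `Frame`.
#' @param path Output path.
#' @export
write_frame_csv <- function(frame, path) {
  ord <- frame$gene_order
  i <- match(ord, frame$summaries$gene_id)
  dt <- data.table::data.table(
    gene_id = ord,
    x = frame$summaries$x[i],
    y = frame$summaries$y[i],
    marker_class = ifelse(is.na(i), "", frame$summaries$marker_class[i]),
    excluded = is.na(i))
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Extent of a frame's placed genes
#'
#' @param frame A `Frame`.
#' @return List with numeric ranges `x` and `y` over included genes.
#' @export
frame_extent <- function(frame) {
  list(x = range(frame$summaries$x), y = range(frame$summaries$y))
}
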