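#' Rendering configuration for headless output
#'
#' @param width,height Image size in pixels.
#' @param xlim,ylim Fixed axis ranges (`NULL` = auto per frame; animations
#'   default to the fixed global extent so motion is comparable across
#'   frames).
#' @param point_cex Marker size.
#' @param groupings Groupings (with colors) to overlay as outlines.
#' @param main Plot title.
#' @return A `RenderConfig`.
#' @export
render_config <- function(width = 800L, height = 600L, xlim = NULL, ylim = NULL,
                          point_cex = 0.7, groupings = list(), main = NULL) {
  if (!is.null(xlim) && any(!is.finite(xlim))) stop("xlim must be finite")
  if (!is.null(ylim) && any(!is.finite(ylim))) stop("ylim must be finite")
  structure(list(width = as.integer(width), height = as.integer(height),
                 xlim = xlim, ylim = ylim, point_cex = point_cex,
                 groupings = groupings, main = main),
            class = "RenderConfig")
}

# marker encodings for missing-data interpolation: full dot for measured
# values, reduced-ink variants for values resting on interpolation
MARKER_PCH <- c(measured = 16L, y_interpolated = 10L, xy_interpolated = 1L)

#' Render a scatter-plot frame to PNG
#'
#' Deterministic, headless rendering: measured genes as full dots,
#' interpolation-based genes with reduced-ink marker variants, grouping
#' outlines as smoothed transparent shapes.
#'
#' @param frame A `Frame`.
#' @param path Output PNG path.
#' @param config A [render_config()].
#' @return `path`, invisibly.
#' @export
render_frame <- function(frame, path, config = render_config()) {
  s <- frame$summaries
  xlim <- if (is.null(config$xlim)) range(s$x) else config$xlim
  ylim <- if (is.null(config$ylim)) range(s$y) else config$ylim
  grDevices::png(path, width = config$width, height = config$height,
                 type = "cairo")
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mar = c(4, 4, if (is.null(config$main)) 1 else 3, 1))
  graphics::plot(NA, xlim = xlim, ylim = ylim,
                 xlab = "change in activity (x)", ylab = "mean activity (y)",
                 main = config$main)
  graphics::abline(v = 0, col = "grey80")
  for (g in config$groupings) {
    o <- compute_outline(frame, g)
    if (!is.null(o)) {
      graphics::polygon(o$polygon,
                        col = grDevices::adjustcolor(o$stroke,
                                                     alpha.f = o$fill_opacity),
                        border = o$stroke, lwd = 2)
    }
  }
  pch <- MARKER_PCH[s$marker_class]
  graphics::points(s$x, s$y, pch = pch, cex = config$point_cex,
                   col = "grey25")
  invisible(path)
}

#' Render a line-chart overview to PNG
#'
#' Overlays value-versus-time profiles for all genes of one condition;
#' segments that bridge filled (missing-interpolated) values are drawn
#' dotted; the current selection interval is shaded; highlighted genes are
#' drawn on top in an accent color (the linked-view counterpart of a
#' scatter-plot selection).
#'
#' @param dataset An `ExpressionDataset`.
#' @param condition Condition label.
#' @param path Output PNG path.
#' @param config A [render_config()].
#' @param selection Optional [interval_selection()] to mark.
#' @param highlight Optional gene ids to accent.
#' @return `path`, invisibly.
#' @export
render_linechart <- function(dataset, condition, path,
                             config = render_config(), selection = NULL,
                             highlight = character()) {
  if (!condition %in% dataset$conditions) {
    stop("lookup error: unknown condition: ", condition)
  }
  dataset <- fill_missing(dataset)
  tt <- dataset$time_points[[condition]]
  V <- dataset$values[[condition]]
  M <- dataset$interpolated[[condition]]
  grDevices::png(path, width = config$width, height = config$height,
                 type = "cairo")
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mar = c(4, 4, if (is.null(config$main)) 1 else 3, 1))
  ylim <- if (is.null(config$ylim)) range(V, na.rm = TRUE) else config$ylim
  graphics::plot(NA, xlim = range(tt), ylim = ylim,
                 xlab = paste0("time (", dataset$time_unit, ")"),
                 ylab = "expression", main = config$main)
  if (!is.null(selection)) {
    graphics::rect(selection$start, ylim[1] - diff(ylim), selection$end,
                   ylim[2] + diff(ylim), col = "#0000FF18", border = NA)
  }
  draw_gene <- function(i, col, lwd) {
    for (k in seq_len(length(tt) - 1L)) {
      if (is.na(V[i, k]) || is.na(V[i, k + 1])) next
      lty <- if (M[i, k] || M[i, k + 1]) 3L else 1L
      graphics::segments(tt[k], V[i, k], tt[k + 1], V[i, k + 1],
                         col = col, lty = lty, lwd = lwd)
    }
  }
  base_col <- grDevices::adjustcolor("grey40", alpha.f = 0.35)
  for (i in seq_len(nrow(V))) draw_gene(i, base_col, 1)
  hi <- match(highlight, dataset$gene_ids)
  hi <- hi[!is.na(hi)]
  for (i in hi) draw_gene(i, "#E41A1C", 2)
  invisible(path)
}

#' Excentric labelling: genes within a circular cursor neighborhood
#'
#' Lists the genes whose frame points lie within `radius` of the cursor,
#' sorted by distance then gene id (deterministic ties).
#'
#' @param frame A `Frame`.
#' @param cx,cy Cursor position in frame coordinates.
#' @param radius Circle radius (> 0); a sensible default is 5% of the axis
#'   span.
#' @return A data.frame `gene_id, x, y, distance`, nearest first.
#' @export
excentric_labels <- function(frame, cx, cy, radius) {
  if (!is.numeric(radius) || radius <= 0) stop("radius must be positive")
  s <- frame$summaries
  d <- sqrt((s$x - cx)^2 + (s$y - cy)^2)
  keep <- which(d <= radius)
  ord <- keep[order(d[keep], s$gene_id[keep])]
  data.frame(gene_id = s$gene_id[ord], x = s$x[ord], y = s$y[ord],
             distance = d[ord], stringsAsFactors = FALSE)
}

#' Export an animation as numbered PNG frames
#'
#' Renders every frame of a selection sweep to
#' `<prefix>_###.png` under `dir`. Axis ranges default to the fixed global
#' extent across all frames, so gene motion is comparable between frames;
#' rendering is deterministic.
#'
#' @param dataset An `ExpressionDataset`.
#' @param condition Condition label.
#' @param mode,steps,width,axis_mode Passed to [animate()].
#' @param dir Output directory (created if needed).
#' @param config A [render_config()]; `xlim`/`ylim` of `NULL` means global
#'   extent.
#' @param prefix File-name prefix.
#' @return Invisibly, a list with `files` and the computed `frames`.
#' @export
export_animation <- function(dataset, condition,
                             mode = c("zero_duration", "fixed_window"),
                             steps = 10L, width = 0, dir,
                             config = render_config(), prefix = "frame",
                             axis_mode = c("difference", "fold_change")) {
  mode <- match.arg(mode)
  axis_mode <- match.arg(axis_mode)
  frames <- animate(dataset, condition, mode, steps, width, axis_mode)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(config$xlim)) {
    config$xlim <- range(unlist(lapply(frames, function(f) f$summaries$x)))
  }
  if (is.null(config$ylim)) {
    config$ylim <- range(unlist(lapply(frames, function(f) f$summaries$y)))
  }
  files <- file.path(dir, sprintf("%s_%03d.png", prefix, seq_along(frames)))
  for (i in seq_along(frames)) render_frame(frames[[i]], files[i], config)
  invisible(list(files = files, frames = frames))
}
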