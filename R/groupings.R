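#' Create a gene grouping
#'
#' @param name Grouping name (unique within a collection).
#' @param members Character vector of gene ids (non-empty).
#' @param color Optional display color (assigned by [assign_colors()]).
#' @return A `GeneGrouping`.
#' @export
create_grouping <- function(name, members, color = NA_character_) {
  members <- as.character(members)
  if (length(members) == 0L) stop("grouping must have at least one member")
  structure(list(name = as.character(name), members = members, color = color),
            class = "GeneGrouping")
}

#' Create a grouping from a gene selection
#'
#' Registers a scatter-plot (e.g. box-query) selection as a named grouping,
#' checking the name against an existing collection.
#'
#' @param name New grouping name.
#' @param genes Non-empty character vector of selected gene ids.
#' @param groupings Existing collection (list of `GeneGrouping`) to check
#'   name uniqueness against.
#' @return A `GeneGrouping`.
#' @export
create_from_selection <- function(name, genes, groupings = list()) {
  if (length(genes) == 0L) stop("empty selection: a grouping needs members")
  if (name %in% vapply(groupings, `[[`, character(1), "name")) {
    stop("duplicate grouping name: ", name)
  }
  create_grouping(name, genes)
}

#' Import gene groupings from a two-column CSV or GMT file
#'
#' Two-column CSV rows are `(group, gene)`; GMT lines are tab-separated
#' `name, description, member...`. Memberships are resolved against the
#' dataset when one is supplied: groupings are still created in full, but
#' unmatched ids are collected in the report rather than silently dropped.
#'
#' @param path Input file.
#' @param format `"two_column_csv"` or `"gmt"`.
#' @param dataset Optional `ExpressionDataset` for membership resolution.
#' @return List with `groupings` (list of `GeneGrouping`) and `unmatched`
#'   (named list of unknown ids per grouping).
#' @export
import_groupings <- function(path, format = c("two_column_csv", "gmt"),
                             dataset = NULL) {
  format <- match.arg(format)
  if (format == "two_column_csv") {
    dt <- data.table::fread(path, header = FALSE, colClasses = "character",
                            sep = ",")
    if (ncol(dt) < 2L) stop("two-column CSV expected (group,gene)")
    nm <- unique(dt[[1]])
    groups <- lapply(nm, function(g) create_grouping(g, dt[[2]][dt[[1]] == g]))
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nm <- vapply(parts, `[`, character(1), 1)
    groups <- lapply(parts, function(p) {
      if (length(p) < 3L) stop("malformed GMT line (need name, description, members)")
      create_grouping(p[1], p[-(1:2)])
    })
  }
  if (anyDuplicated(nm)) {
    stop("duplicate group names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  unmatched <- stats::setNames(vector("list", length(groups)), nm)
  if (!is.null(dataset)) {
    for (i in seq_along(groups)) {
      unmatched[[i]] <- setdiff(groups[[i]]$members, dataset$gene_ids)
    }
  }
  list(groupings = groups, unmatched = unmatched)
}

#' Export gene groupings
#'
#' Writes the same two-column CSV or GMT layout read by
#' [import_groupings()]; an import of the export preserves membership and
#' order.
#'
#' @param groupings List of `GeneGrouping`.
#' @param path Output file.
#' @param format `"two_column_csv"` or `"gmt"`.
#' @export
export_groupings <- function(groupings, path,
                             format = c("two_column_csv", "gmt")) {
  format <- match.arg(format)
  if (format == "two_column_csv") {
    dt <- data.table::rbindlist(lapply(groupings, function(g)
      data.table::data.table(V1 = g$name, V2 = g$members)))
    data.table::fwrite(dt, path, col.names = FALSE)
  } else {
    writeLines(vapply(groupings, function(g)
      paste(c(g$name, "", g$members), collapse = "\t"), character(1)), path)
  }
  invisible(path)
}

# fixed qualitative palette (Brewer-style Set1, four slots) embedded as
# constants so output is reproducible without external lookups
GROUP_PALETTE <- c("#E41A1C", "#377EB8", "#4DAF4A", "#984EA3")

#' Assign qualitative colors to groupings for simultaneous overlay
#'
#' Up to `max_overlay` (default four) groupings can be overlaid at once;
#' slots from a fixed four-color qualitative palette are assigned
#' deterministically by display order. More simultaneous overlays than
#' palette slots is refused.
#'
#' @param groupings List of `GeneGrouping` flagged for display, in display
#'   order.
#' @param max_overlay Maximum simultaneous overlays (4).
#' @return The groupings with distinct `color` slots filled in.
#' @export
assign_colors <- function(groupings, max_overlay = 4L) {
  if (length(groupings) > max_overlay) {
    stop("at most ", max_overlay, " groupings can be overlaid simultaneously; ",
         "display fewer groups at a time")
  }
  for (i in seq_along(groupings)) groupings[[i]]$color <- GROUP_PALETTE[i]
  groupings
}

# Chaikin corner-cutting on a closed polygon (n x 2 matrix)
chaikin <- function(P, iterations = 2L) {
  for (it in seq_len(iterations)) {
    nxt <- rbind(P[-1, , drop = FALSE], P[1, , drop = FALSE])
    Q <- matrix(NA_real_, nrow = 2L * nrow(P), ncol = 2L)
    Q[seq(1, nrow(Q), by = 2), ] <- 0.75 * P + 0.25 * nxt
    Q[seq(2, nrow(Q), by = 2), ] <- 0.25 * P + 0.75 * nxt
    P <- Q
  }
  P
}

#' Smoothed outline around a grouping's frame points
#'
#' The overlay geometry: the convex hull of the member points, offset
#' outward by `padding` (so even a single point or collinear points give a
#' positive-area outline) and smoothed by iterative corner-cutting into a
#' closed curve. All member points lie strictly inside; non-members may fall
#' inside too — the known false-positive effect of circling genes that do
#' not belong, accepted for this encoding.
#'
#' @param frame A `Frame`.
#' @param grouping A `GeneGrouping`.
#' @param padding Outward offset in plot units; defaults to 2% of the
#'   larger frame axis span.
#' @param smoothing Corner-cutting iterations.
#' @return A `GroupOutline` (list with `polygon` matrix, `stroke`,
#'   `fill_opacity`), or `NULL` with a warning when every member is
#'   frame-excluded.
#' @export
compute_outline <- function(frame, grouping, padding = NULL, smoothing = 2L) {
  s <- frame$summaries
  idx <- match(grouping$members, s$gene_id)
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0L) {
    warning("all members of grouping '", grouping$name,
            "' are excluded from this frame")
    return(NULL)
  }
  if (is.null(padding)) {
    ext <- frame_extent(frame)
    padding <- 0.02 * max(diff(ext$x), diff(ext$y), .Machine$double.eps)
  }
  pts <- cbind(s$x[idx], s$y[idx])
  ang <- seq(0, 2 * pi, length.out = 25L)[-25L]
  disc <- cbind(cos(ang), sin(ang)) * padding
  cloud <- cbind(rep(pts[, 1], each = nrow(disc)) + disc[, 1],
                 rep(pts[, 2], each = nrow(disc)) + disc[, 2])
  hull <- grDevices::chull(cloud)
  poly <- cloud[rev(hull), , drop = FALSE]  # chull is clockwise; reverse
  poly <- chaikin(poly, smoothing)
  structure(list(polygon = poly,
                 stroke = if (is.na(grouping$color)) GROUP_PALETTE[1]
                          else grouping$color,
                 fill_opacity = 0.25, name = grouping$name),
            class = "GroupOutline")
}

#' Point-in-polygon test (ray casting)
#'
#' @param x,y Point coordinates (vectors).
#' @param polygon Closed polygon as an `n x 2` matrix (not repeated at the
#'   end).
#' @return Logical vector: `TRUE` for points strictly inside.
#' @export
point_in_polygon <- function(x, y, polygon) {
  px <- polygon[, 1]; py <- polygon[, 2]
  n <- length(px)
  jx <- c(px[n], px[-n]); jy <- c(py[n], py[-n])
  vapply(seq_along(x), function(i) {
    crosses <- ((py > y[i]) != (jy > y[i])) &
      (x[i] < (jx - px) * (y[i] - py) / (jy - py) + px)
    sum(crosses) %% 2L == 1L
  }, logical(1))
}

#' Area of a closed polygon (shoelace formula)
#'
#' Positive for anticlockwise vertex order.
#'
#' @param polygon An `n x 2` matrix of vertices.
#' @return Signed area.
#' @export
polygon_signed_area <- function(polygon) {
  x <- polygon[, 1]; y <- polygon[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}
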