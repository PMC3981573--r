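#' Axis-aligned box query over one frame
#'
#' A box query selects the genes whose interval summary for a snapped
#' selection falls inside up to four closed bounds (`x_min`, `x_max`,
#' `y_min`, `y_max`; an absent bound is unbounded). At least one bound must
#' be present, and present `min` must be below present `max` per axis.
#'
#' @param condition Condition label.
#' @param start,end Snapped interval endpoints (grid times).
#' @param axis_mode `"difference"` or `"fold_change"`.
#' @param x_min,x_max,y_min,y_max Optional numeric bounds (`NULL` =
#'   unbounded).
#' @return A `BoxQuery`.
#' @export
box_query <- function(condition, start, end,
                      axis_mode = c("difference", "fold_change"),
                      x_min = NULL, x_max = NULL, y_min = NULL, y_max = NULL) {
  axis_mode <- match.arg(axis_mode)
  edges <- list(x_min = x_min, x_max = x_max, y_min = y_min, y_max = y_max)
  if (all(vapply(edges, is.null, logical(1)))) {
    stop("box query needs at least one bound")
  }
  if (!is.null(x_min) && !is.null(x_max) && x_min >= x_max) {
    stop("x_min must be below x_max")
  }
  if (!is.null(y_min) && !is.null(y_max) && y_min >= y_max) {
    stop("y_min must be below y_max")
  }
  structure(list(condition = as.character(condition), start = as.numeric(start),
                 end = as.numeric(end), axis_mode = axis_mode,
                 x_min = x_min, x_max = x_max, y_min = y_min, y_max = y_max),
            class = c("BoxQuery", "PatternExpression"))
}

#' Boolean combinators for box queries
#'
#' Build a Boolean expression tree over [box_query()] leaves. `q_and` and
#' `q_or` take two or more operands; `q_not` is unary and complements
#' against the genes that have data for its operand's frames (a gene is
#' never selected purely for lacking data).
#'
#' @param ... Two or more `PatternExpression`s.
#' @return A `PatternExpression`.
#' @export
q_and <- function(...) make_node("AND", list(...))

#' @rdname q_and
#' @export
q_or <- function(...) make_node("OR", list(...))

#' @rdname q_and
#' @param expr A `PatternExpression`.
#' @export
q_not <- function(expr) {
  stopifnot(inherits(expr, "PatternExpression"))
  structure(list(op = "NOT", args = list(expr)), class = "PatternExpression")
}

make_node <- function(op, args) {
  if (length(args) < 2L) stop(op, " needs at least two operands")
  ok <- vapply(args, inherits, logical(1), what = "PatternExpression")
  if (!all(ok)) stop("operands must be PatternExpressions")
  structure(list(op = op, args = args), class = "PatternExpression")
}

fmt_num <- function(x) {
  if (is.null(x)) return("*")
  sprintf("%.15g", x)
}

#' Canonical text serialization of a pattern expression
#'
#' Box leaves print as
#' `BOX{condition=...;start=...;end=...;mode=...;x_min=...;x_max=...;y_min=...;y_max=...}`
#' (absent bounds as `*`); `AND`/`OR` nodes are flattened and their operands
#' sorted, so semantically equal expressions serialize identically.
#'
#' @param expr A `PatternExpression`.
#' @return A character scalar.
#' @export
canonical_expression <- function(expr) {
  if (inherits(expr, "BoxQuery")) {
    return(paste0("BOX{condition=", expr$condition,
                  ";start=", fmt_num(expr$start), ";end=", fmt_num(expr$end),
                  ";mode=", expr$axis_mode,
                  ";x_min=", fmt_num(expr$x_min), ";x_max=", fmt_num(expr$x_max),
                  ";y_min=", fmt_num(expr$y_min), ";y_max=", fmt_num(expr$y_max),
                  "}"))
  }
  if (expr$op == "NOT") {
    return(paste0("NOT(", canonical_expression(expr$args[[1]]), ")"))
  }
  # flatten nested nodes of the same operator, then sort for canonical order
  flat <- list()
  for (a in expr$args) {
    if (!inherits(a, "BoxQuery") && identical(a$op, expr$op)) {
      flat <- c(flat, a$args)
    } else flat <- c(flat, list(a))
  }
  parts <- sort(vapply(flat, canonical_expression, character(1)))
  paste0(expr$op, "(", paste(parts, collapse = ","), ")")
}

# split a comma-separated argument list at nesting depth zero
split_args <- function(s) {
  depth <- 0L; out <- character(); last <- 1L
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch %in% c("(", "{")) depth <- depth + 1L
    if (ch %in% c(")", "}")) depth <- depth - 1L
    if (ch == "," && depth == 0L) {
      out <- c(out, substr(s, last, i - 1L)); last <- i + 1L
    }
  }
  c(out, substr(s, last, nchar(s)))
}

#' Parse the canonical expression text
#'
#' Inverse of [canonical_expression()].
#'
#' @param text Canonical expression string.
#' @return A `PatternExpression`.
#' @export
parse_expression <- function(text) {
  text <- trimws(text)
  if (startsWith(text, "BOX{")) {
    body <- sub("^BOX\\{", "", sub("\\}$", "", text))
    kv <- strsplit(split_args(gsub(";", ",", body)), "=", fixed = TRUE)
    vals <- stats::setNames(vapply(kv, `[`, character(1), 2),
                            vapply(kv, `[`, character(1), 1))
    num <- function(k) {
      v <- vals[[k]]
      if (is.null(v) || v == "*") NULL else as.numeric(v)
    }
    return(box_query(vals[["condition"]], as.numeric(vals[["start"]]),
                     as.numeric(vals[["end"]]), vals[["mode"]],
                     x_min = num("x_min"), x_max = num("x_max"),
                     y_min = num("y_min"), y_max = num("y_max")))
  }
  m <- regmatches(text, regexec("^(AND|OR|NOT)\\((.*)\\)$", text))[[1]]
  if (length(m) != 3L) stop("cannot parse expression: ", text)
  args <- lapply(split_args(m[3]), parse_expression)
  if (m[2] == "NOT") {
    if (length(args) != 1L) stop("NOT is unary")
    return(q_not(args[[1]]))
  }
  make_node(m[2], args)
}

# frame cache keyed by (condition, start, end, mode)
frame_for_query <- function(dataset, q, cache) {
  key <- paste(q$condition, fmt_num(q$start), fmt_num(q$end), q$axis_mode,
               sep = "\r")
  if (is.null(cache[[key]])) {
    tt <- dataset$time_points[[q$condition]]
    if (is.null(tt)) stop("lookup error: unknown condition: ", q$condition)
    on_grid <- function(t) any(abs(tt - t) < 1e-9)
    if (!on_grid(q$start) || !on_grid(q$end)) {
      stop("query error: snap before querying (interval endpoints must be grid times)")
    }
    sel <- interval_selection(q$condition, q$start, q$end, snapped = TRUE)
    cache[[key]] <- frame_at(dataset, sel, q$axis_mode)
  }
  cache[[key]]
}

#' Evaluate a box query against a dataset
#'
#' Bounds are closed (`min <= v <= max`); genes excluded from the frame
#' never match. The query's interval must coincide with grid times (snapped);
#' otherwise a query error is raised.
#'
#' @param dataset An `ExpressionDataset`.
#' @param query A [box_query()].
#' @return Character vector of matching gene ids.
#' @export
evaluate_box <- function(dataset, query) {
  cache <- new.env(parent = emptyenv())
  eval_leaf(dataset, query, cache)$genes
}

eval_leaf <- function(dataset, q, cache) {
  fr <- frame_for_query(dataset, q, cache)
  s <- fr$summaries
  keep <- rep(TRUE, nrow(s))
  if (!is.null(q$x_min)) keep <- keep & s$x >= q$x_min
  if (!is.null(q$x_max)) keep <- keep & s$x <= q$x_max
  if (!is.null(q$y_min)) keep <- keep & s$y >= q$y_min
  if (!is.null(q$y_max)) keep <- keep & s$y <= q$y_max
  list(genes = s$gene_id[keep], universe = s$gene_id)
}

#' Evaluate a Boolean pattern expression
#'
#' Set algebra over box-query results: `AND` intersects, `OR` unites, and
#' `NOT` complements against the genes that have data in every frame of its
#' operand (so genes lacking data are never selected by negation).
#'
#' @param dataset An `ExpressionDataset`.
#' @param expression A `PatternExpression`.
#' @return Character vector of gene ids (dataset order).
#' @export
evaluate_expression <- function(dataset, expression) {
  cache <- new.env(parent = emptyenv())
  r <- eval_node(dataset, expression, cache)
  dataset$gene_ids[dataset$gene_ids %in% r$genes]
}

eval_node <- function(dataset, e, cache) {
  if (inherits(e, "BoxQuery")) return(eval_leaf(dataset, e, cache))
  parts <- lapply(e$args, eval_node, dataset = dataset, cache = cache)
  universe <- Reduce(intersect, lapply(parts, `[[`, "universe"))
  genes <- switch(e$op,
                  AND = Reduce(intersect, lapply(parts, `[[`, "genes")),
                  OR = Reduce(union, lapply(parts, `[[`, "genes")),
                  NOT = setdiff(parts[[1]]$universe, parts[[1]]$genes))
  list(genes = genes, universe = universe)
}

#' "Nice" rounding step for query thresholds
#'
#' The rounding grid step is the axis span divided by 100, floored to the
#' nearest 1-2-5 x 10^k step — the granularity of typical axis labels. A
#' span of 10 gives 0.1; a span of 7 gives 0.05.
#'
#' @param span Positive axis span.
#' @return The step.
#' @export
nice_step <- function(span) {
  if (!is.finite(span) || span <= 0) stop("axis span must be finite and positive")
  raw <- span / 100
  k <- floor(log10(raw))
  for (kk in c(k + 1, k)) {
    for (m in c(5, 2, 1)) {
      step <- m * 10^kk
      if (step <= raw * (1 + 1e-9)) return(step)
    }
  }
  10^k
}

round_to_step <- function(v, step) {
  r <- round(v / step) * step
  round(r, max(0, -floor(log10(step)) + 1))
}

#' Round a box query's edges to the sharing grid
#'
#' Query parameters are restricted to rounded values so stored patterns are
#' understandable when recalled or shared: each present edge is snapped to
#' the nearest point of the [nice_step()] grid of its axis. Rounding is
#' idempotent. A box whose edges coincide after rounding is a query error.
#'
#' @param query A [box_query()] with raw (drag) coordinates.
#' @param x_range,y_range Numeric length-2 axis ranges of the frame.
#' @return The rounded `BoxQuery`.
#' @export
round_edges <- function(query, x_range, y_range) {
  sx <- nice_step(diff(range(x_range)))
  sy <- nice_step(diff(range(y_range)))
  for (k in c("x_min", "x_max")) {
    if (!is.null(query[[k]])) query[[k]] <- round_to_step(query[[k]], sx)
  }
  for (k in c("y_min", "y_max")) {
    if (!is.null(query[[k]])) query[[k]] <- round_to_step(query[[k]], sy)
  }
  if ((!is.null(query$x_min) && !is.null(query$x_max) &&
       query$x_min >= query$x_max) ||
      (!is.null(query$y_min) && !is.null(query$y_max) &&
       query$y_min >= query$y_max)) {
    stop("query error: degenerate box after rounding")
  }
  query
}

#' Drop superfluous box edges
#'
#' An edge at or beyond the data extent on its side constrains nothing and
#' is removed (made unbounded), leaving only the thresholds the user
#' actually set. Removing every edge would make the query select everything,
#' which is an error. Idempotent.
#'
#' @param query A [box_query()].
#' @param extent Frame extent as returned by [frame_extent()].
#' @return The simplified `BoxQuery`.
#' @export
simplify_query <- function(query, extent) {
  if (!is.null(query$x_min) && query$x_min <= extent$x[1]) query["x_min"] <- list(NULL)
  if (!is.null(query$x_max) && query$x_max >= extent$x[2]) query["x_max"] <- list(NULL)
  if (!is.null(query$y_min) && query$y_min <= extent$y[1]) query["y_min"] <- list(NULL)
  if (!is.null(query$y_max) && query$y_max >= extent$y[2]) query["y_max"] <- list(NULL)
  if (is.null(query$x_min) && is.null(query$x_max) &&
      is.null(query$y_min) && is.null(query$y_max)) {
    stop("query error: query selects everything (all edges superfluous)")
  }
  query
}

#' Create a shareable pattern record
#'
#' A pattern is a stored finding: a Boolean expression over box queries,
#' the identity of the dataset it was formed on, the transform provenance
#' under which coordinates were computed, an optional cached result gene
#' list and free-text annotations.
#'
#' @param pattern_id Identifier.
#' @param dataset An `ExpressionDataset` (supplies dataset id and transform
#'   provenance), or a character dataset id.
#' @param expression A `PatternExpression`.
#' @param result_genes Optional cached result (gene ids).
#' @param annotations Free text.
#' @param created Timestamp string; defaults to the current UTC time.
#' @param transforms Transform provenance; defaults to the dataset's log, or
#'   `"raw"` when empty.
#' @return A `Pattern`.
#' @export
pattern <- function(pattern_id, dataset, expression, result_genes = NULL,
                    annotations = "", created = NULL, transforms = NULL) {
  if (inherits(dataset, "ExpressionDataset")) {
    did <- dataset$dataset_id
    if (is.null(transforms)) {
      transforms <- if (length(dataset$transform_log))
        dataset$transform_log else "raw"
    }
  } else {
    did <- as.character(dataset)
    if (is.null(transforms)) transforms <- "raw"
  }
  if (is.null(created)) {
    created <- format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  }
  structure(list(pattern_id = as.character(pattern_id), dataset_id = did,
                 transforms = as.character(transforms),
                 expression = expression,
                 result_genes = result_genes,
                 annotations = as.character(annotations), created = created),
            class = "Pattern")
}

#' Evaluate a pattern against a dataset
#'
#' Refuses to evaluate when the dataset identifier differs from the
#' pattern's provenance unless `override = TRUE`.
#'
#' @param dataset An `ExpressionDataset`.
#' @param pat A `Pattern`.
#' @param override Evaluate despite a dataset-id mismatch.
#' @return Gene ids matching the pattern's expression.
#' @export
evaluate_pattern <- function(dataset, pat, override = FALSE) {
  if (!identical(dataset$dataset_id, pat$dataset_id) && !override) {
    stop("dataset_id mismatch: pattern was formed on '", pat$dataset_id,
         "', dataset is '", dataset$dataset_id,
         "' (pass override = TRUE to evaluate anyway)")
  }
  evaluate_expression(dataset, pat$expression)
}

PATTERN_FORMAT_VERSION <- 1L

#' Save / load pattern files
#'
#' Patterns serialize to versioned JSON (UTF-8) holding the format version,
#' dataset id, transform provenance, the canonical expression text, cached
#' results, annotations and creation time. A save/load round trip is
#' canonical-form identical. Loading a file with an unknown format version
#' is a format error; loading against a dataset with a different id warns
#' (evaluation is then refused until overridden).
#'
#' @param pat A `Pattern`.
#' @param path File path (conventionally `*.pattern.json`).
#' @export
save_pattern <- function(pat, path) {
  obj <- list(format_version = PATTERN_FORMAT_VERSION,
              pattern_id = pat$pattern_id,
              dataset_id = pat$dataset_id,
              transforms = as.list(pat$transforms),
              expression = canonical_expression(pat$expression),
              result_genes = as.list(pat$result_genes),
              annotations = pat$annotations,
              created = pat$created)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_pattern
#' @param dataset Optional dataset to check the pattern's provenance
#'   against on load.
#' @export
load_pattern <- function(path, dataset = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format_version) ||
      obj$format_version != PATTERN_FORMAT_VERSION) {
    stop("format error: unknown pattern file version: ", obj$format_version)
  }
  p <- pattern(obj$pattern_id, obj$dataset_id,
               parse_expression(obj$expression),
               result_genes = if (length(obj$result_genes))
                 as.character(obj$result_genes) else NULL,
               annotations = obj$annotations, created = obj$created,
               transforms = as.character(obj$transforms))
  if (!is.null(dataset) && !identical(dataset$dataset_id, p$dataset_id)) {
    warning("dataset_id mismatch: pattern '", p$dataset_id, "' vs dataset '",
            dataset$dataset_id, "'")
  }
  p
}

#' Replace one leaf of a pattern's expression
#'
#' Refining a pattern swaps a single box-query leaf (leaves numbered in
#' depth-first order) and invalidates the cached result genes.
#'
#' @param pat A `Pattern`.
#' @param leaf_index Which leaf to replace (depth-first, 1-based).
#' @param new_box The replacement [box_query()].
#' @return The refined `Pattern`.
#' @export
refine_pattern <- function(pat, leaf_index, new_box) {
  stopifnot(inherits(new_box, "BoxQuery"))
  counter <- new.env(parent = emptyenv()); counter$i <- 0L
  rec <- function(e) {
    if (inherits(e, "BoxQuery")) {
      counter$i <- counter$i + 1L
      if (counter$i == leaf_index) return(new_box)
      return(e)
    }
    e$args <- lapply(e$args, rec)
    e
  }
  pat$expression <- rec(pat$expression)
  if (counter$i < leaf_index) stop("leaf_index out of range")
  pat$result_genes <- NULL
  pat
}

#' Export a pattern's result genes, one id per line
#'
#' @param pat A `Pattern` with cached `result_genes` (or supply `genes`).
#' @param path Output path.
#' @param genes Optional explicit gene ids to write.
#' @export
export_genes <- function(pat, path, genes = pat$result_genes) {
  if (is.null(genes)) stop("no result genes to export (evaluate the pattern first)")
  writeLines(as.character(genes), path)
  invisible(path)
}
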