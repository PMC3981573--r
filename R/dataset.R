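#' Construct an expression time-course dataset
#'
#' The central container of the package: one expression value per
#' (gene, condition, time point), with replicates already collapsed, a
#' missing-value mask (`NA` cells), per-condition time grids and an ordered
#' log of the transforms applied since import. Conditions may have different
#' time grids; alignment across conditions is by time value, never by index.
#'
#' @param dataset_id Character scalar identifying the dataset (used for
#'   pattern provenance checks).
#' @param gene_ids Character vector of unique gene identifiers; row order is
#'   preserved everywhere (frames, exports).
#' @param conditions Character vector of condition labels.
#' @param time_points Named list (one entry per condition) of strictly
#'   increasing numeric time values, or a single numeric vector shared by all
#'   conditions.
#' @param values Named list (per condition) of numeric matrices
#'   `genes x time points` (`NA` = missing), or a single matrix for a
#'   single-condition dataset.
#' @param annotations Optional character vector of per-gene annotations.
#' @param time_labels Optional named list of per-condition display labels for
#'   the time points (e.g. developmental-stage labels); defaults to
#'   `"t<value>"`.
#' @param time_unit Unit label for the time axis (e.g. `"days"`).
#' @param replicate_sets Optional named list (per condition) of lists giving,
#'   for each time point, the source column identifiers collapsed into that
#'   value.
#' @param replicate_variance Optional named list (per condition) of matrices
#'   of per-slot replicate variances (used by error-weighted reference
#'   rescaling).
#' @param transform_log Character vector of canonical transform
#'   specifications already applied (normally empty at import).
#'
#' @return An object of class `ExpressionDataset`.
#' @export
expression_dataset <- function(dataset_id, gene_ids, conditions, time_points,
                               values, annotations = NULL, time_labels = NULL,
                               time_unit = "time", replicate_sets = NULL,
                               replicate_variance = NULL,
                               transform_log = character()) {
  gene_ids <- as.character(gene_ids)
  conditions <- as.character(conditions)
  if (!is.list(time_points)) {
    time_points <- stats::setNames(rep(list(as.numeric(time_points)),
                                       length(conditions)), conditions)
  }
  if (is.matrix(values)) values <- stats::setNames(list(values), conditions)
  values <- lapply(values, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    rownames(m) <- gene_ids
    m
  })
  if (is.null(time_labels)) {
    time_labels <- lapply(time_points, function(tt) paste0("t", format(tt, trim = TRUE)))
  }
  ds <- structure(list(
    dataset_id = as.character(dataset_id)[1],
    gene_ids = gene_ids,
    annotations = annotations,
    conditions = conditions,
    time_points = time_points,
    time_labels = time_labels,
    time_unit = time_unit,
    values = values,
    interpolated = NULL,
    replicate_sets = replicate_sets,
    replicate_variance = replicate_variance,
    raw_values = values,
    transform_log = as.character(transform_log)
  ), class = "ExpressionDataset")
  rep <- validate_dataset(ds)
  if (!rep$pass) {
    stop("invalid ExpressionDataset: ", paste(rep$failures, collapse = "; "))
  }
  ds
}

#' Validate an expression dataset and summarize its structure
#'
#' Checks the container invariants (strictly increasing time grids with at
#' least two points per condition, a value slot for every gene/condition/time
#' combination, unique gene identifiers) and reports basic counts plus the
#' missing-value fraction per condition. Violations are reported, never
#' thrown.
#'
#' @param dataset An `ExpressionDataset` (or a list with the same fields).
#' @return A list of class `dataset_report` with elements `pass`, `failures`,
#'   `n_genes`, `n_conditions`, `n_time_points` (named per condition) and
#'   `missing_fraction` (named per condition).
#' @export
validate_dataset <- function(dataset) {
  f <- character()
  gid <- dataset$gene_ids
  if (anyDuplicated(gid)) {
    f <- c(f, paste0("duplicate gene ids: ",
                     paste(unique(gid[duplicated(gid)]), collapse = ", ")))
  }
  conds <- dataset$conditions
  if (length(conds) < 1L) f <- c(f, "no conditions")
  ntp <- stats::setNames(integer(length(conds)), conds)
  mfrac <- stats::setNames(numeric(length(conds)), conds)
  for (cn in conds) {
    tt <- dataset$time_points[[cn]]
    if (is.null(tt)) { f <- c(f, paste0("condition '", cn, "' has no time points")); next }
    ntp[cn] <- length(tt)
    if (length(tt) < 2L) f <- c(f, paste0("condition '", cn, "' has fewer than 2 time points"))
    if (is.unsorted(tt, strictly = TRUE)) {
      f <- c(f, paste0("time points not strictly increasing in condition '", cn, "'"))
    }
    v <- dataset$values[[cn]]
    if (is.null(v) || nrow(v) != length(gid) || ncol(v) != length(tt)) {
      f <- c(f, paste0("value matrix for condition '", cn,
                       "' is not genes x time points"))
    } else {
      mfrac[cn] <- mean(is.na(v))
    }
  }
  structure(list(pass = length(f) == 0L, failures = f,
                 n_genes = length(gid), n_conditions = length(conds),
                 n_time_points = ntp, missing_fraction = mfrac),
            class = "dataset_report")
}

#' @export
print.dataset_report <- function(x, ...) {
  cat("ExpressionDataset report:", if (x$pass) "PASS" else "FAIL", "\n")
  cat("  genes:", x$n_genes, " conditions:", x$n_conditions, "\n")
  cat("  time points:", paste(names(x$n_time_points), x$n_time_points,
                              sep = "=", collapse = ", "), "\n")
  cat("  missing fraction:",
      paste(names(x$missing_fraction),
            signif(x$missing_fraction, 3), sep = "=", collapse = ", "), "\n")
  if (!x$pass) cat("  failures:\n", paste0("   - ", x$failures, "\n"), sep = "")
  invisible(x)
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat("ExpressionDataset '", x$dataset_id, "': ", length(x$gene_ids),
      " genes, ", length(x$conditions), " condition(s)\n", sep = "")
  for (cn in x$conditions) {
    cat("  ", cn, ": ", length(x$time_points[[cn]]), " time points (",
        x$time_unit, " ", format(min(x$time_points[[cn]])), "..",
        format(max(x$time_points[[cn]])), "), ",
        signif(mean(is.na(x$values[[cn]])) * 100, 3), "% missing\n", sep = "")
  }
  if (length(x$transform_log)) {
    cat("  transforms:", paste(x$transform_log, collapse = " -> "), "\n")
  }
  invisible(x)
}

# resolve a time-point reference (label, "t<value>" or numeric time) to a
# column index within one condition; NA if unresolvable
resolve_time_point <- function(dataset, condition, reference) {
  tt <- dataset$time_points[[condition]]
  lb <- dataset$time_labels[[condition]]
  if (is.numeric(reference)) {
    i <- which(abs(tt - reference) < 1e-9)
    return(if (length(i)) i[1] else NA_integer_)
  }
  i <- which(lb == reference)
  if (length(i)) return(i[1])
  suppressWarnings(num <- as.numeric(sub("^t", "", reference)))
  if (!is.na(num)) {
    i <- which(abs(tt - num) < 1e-9)
    if (length(i)) return(i[1])
  }
  NA_integer_
}
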