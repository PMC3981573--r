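#' Describe the role of each column of a native CSV file
#'
#' A column mapping assigns every column of a native CSV file a role:
#' exactly one `gene_id` column, optional `annotation` columns, `ignore`
#' columns, and `measurement` columns carrying a condition label, a numeric
#' time value and a replicate index. Measurement columns sharing
#' (condition, time) are replicates and are collapsed at import.
#'
#' @param column Character vector of column names.
#' @param role One of `"gene_id"`, `"annotation"`, `"ignore"`,
#'   `"measurement"` per column.
#' @param condition,time,replicate Condition label, numeric time value and
#'   replicate index for measurement columns (`NA` otherwise).
#' @return A `data.frame` of class `ColumnMapping`.
#' @export
column_mapping <- function(column, role, condition = NA_character_,
                           time = NA_real_, replicate = NA_integer_) {
  m <- data.frame(column = as.character(column), role = as.character(role),
                  condition = as.character(condition), time = as.numeric(time),
                  replicate = as.integer(replicate), stringsAsFactors = FALSE)
  bad <- setdiff(m$role, c("gene_id", "annotation", "ignore", "measurement"))
  if (length(bad)) stop("unknown column role(s): ", paste(bad, collapse = ", "))
  if (sum(m$role == "gene_id") != 1L) stop("exactly one gene_id column required")
  meas <- m[m$role == "measurement", ]
  if (any(!is.finite(meas$time))) {
    stop("measurement column(s) without a finite time value: ",
         paste(meas$column[!is.finite(meas$time)], collapse = ", "))
  }
  class(m) <- c("ColumnMapping", "data.frame")
  m
}

#' Infer a column mapping from native CSV headers
#'
#' Measurement headers follow the native dialect
#' `"<condition>|<time>|<replicate>"`; a header named `gene_id` (or the first
#' column) maps to the gene identifier, `annotation` to per-gene text, and
#' anything else is ignored.
#'
#' @param headers Character vector of column names.
#' @return A [column_mapping()].
#' @export
guess_mapping <- function(headers) {
  role <- character(length(headers))
  condition <- rep(NA_character_, length(headers))
  time <- rep(NA_real_, length(headers))
  replicate <- rep(NA_integer_, length(headers))
  for (i in seq_along(headers)) {
    h <- headers[i]
    if (grepl("|", h, fixed = TRUE)) {
      parts <- strsplit(h, "|", fixed = TRUE)[[1]]
      if (length(parts) < 2L) stop("malformed measurement header: ", h)
      role[i] <- "measurement"
      condition[i] <- parts[1]
      time[i] <- suppressWarnings(as.numeric(parts[2]))
      replicate[i] <- if (length(parts) >= 3L)
        suppressWarnings(as.integer(parts[3])) else 1L
      if (!is.finite(time[i])) stop("non-numeric time in header: ", h)
    } else if (h == "annotation") {
      role[i] <- "annotation"
    } else if (h == "gene_id" || i == 1L) {
      role[i] <- "gene_id"
    } else {
      role[i] <- "ignore"
    }
  }
  column_mapping(headers, role, condition, time, replicate)
}

MISSING_SPELLINGS <- c("", "NA", "null")

# parse a character matrix of measurement cells; missing spellings -> NA,
# anything else non-numeric is an error (CSV) or NA (SOFT, lenient = TRUE)
parse_cells <- function(chr, lenient = FALSE, colnames_for_error = NULL) {
  chr <- trimws(chr)
  is_missing <- chr %in% MISSING_SPELLINGS | is.na(chr)
  num <- suppressWarnings(as.numeric(chr))
  bad <- !is_missing & is.na(num)
  if (any(bad) && !lenient) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    cn <- if (!is.null(colnames_for_error)) colnames_for_error[idx[2]] else idx[2]
    stop("non-numeric measurement cell '", chr[which(bad)[1]],
         "' at row ", idx[1], ", column ", cn)
  }
  num[is_missing | bad] <- NA_real_
  num
}

# collapse replicate columns into per-(condition, time) means, ignoring NA;
# also records source column ids and replicate variances
collapse_measurements <- function(raw, cond, time, col_ids, gene_ids) {
  conds <- unique(cond)
  values <- list(); rsets <- list(); rvar <- list(); tps <- list()
  for (cn in conds) {
    sel <- which(cond == cn)
    tt <- sort(unique(time[sel]))
    V <- matrix(NA_real_, nrow = length(gene_ids), ncol = length(tt))
    S <- matrix(NA_real_, nrow = length(gene_ids), ncol = length(tt))
    sets <- vector("list", length(tt))
    for (k in seq_along(tt)) {
      cols <- sel[abs(time[sel] - tt[k]) < 1e-9]
      block <- raw[, cols, drop = FALSE]
      nrep <- rowSums(!is.na(block))
      V[, k] <- ifelse(nrep > 0, rowMeans(block, na.rm = TRUE), NA_real_)
      if (length(cols) > 1L) {
        S[, k] <- ifelse(nrep > 1, apply(block, 1, stats::var, na.rm = TRUE),
                         NA_real_)
      }
      sets[[k]] <- col_ids[cols]
    }
    rownames(V) <- gene_ids
    values[[cn]] <- V; rvar[[cn]] <- S; rsets[[cn]] <- sets; tps[[cn]] <- tt
  }
  list(values = values, replicate_sets = rsets, replicate_variance = rvar,
       time_points = tps, conditions = conds)
}

#' Read the native CSV expression dialect
#'
#' One gene per row; a header row; measurement column headers encoded as
#' `"<condition>|<time>|<replicate>"`. Replicate columns sharing
#' (condition, time) are collapsed to their arithmetic mean, ignoring missing
#' replicates; a slot whose replicates are all missing stays missing. Time
#' points are sorted ascending regardless of column order. Missing cells may
#' be spelled `""`, `"NA"` or `"null"`; any other non-numeric cell is a parse
#' error naming the row and column.
#'
#' @param path Path to the CSV file.
#' @param mapping Optional [column_mapping()]; inferred from the headers via
#'   [guess_mapping()] when omitted.
#' @param dataset_id Dataset identifier; defaults to the file name.
#' @return An [expression_dataset()].
#' @export
read_csv_native <- function(path, mapping = NULL, dataset_id = NULL) {
  dt <- data.table::fread(path, colClasses = "character", sep = ",",
                          header = TRUE, na.strings = NULL)
  headers <- names(dt)
  if (is.null(mapping)) mapping <- guess_mapping(headers)
  missing_cols <- setdiff(headers, mapping$column)
  if (length(missing_cols)) {
    stop("mapping does not cover column(s): ", paste(missing_cols, collapse = ", "))
  }
  m <- mapping[match(headers, mapping$column), ]
  gene_ids <- as.character(dt[[which(m$role == "gene_id")]])
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  ann_col <- which(m$role == "annotation")
  annotations <- if (length(ann_col)) as.character(dt[[ann_col[1]]]) else NULL
  meas <- which(m$role == "measurement")
  raw <- matrix(NA_real_, nrow = length(gene_ids), ncol = length(meas))
  if (length(gene_ids)) {
    chr <- as.matrix(dt[, meas, with = FALSE])
    raw <- matrix(parse_cells(chr, colnames_for_error = headers[meas]),
                  nrow = length(gene_ids))
  }
  cm <- collapse_measurements(raw, m$condition[meas], m$time[meas],
                              headers[meas], gene_ids)
  expression_dataset(
    dataset_id = if (is.null(dataset_id)) basename(path) else dataset_id,
    gene_ids = gene_ids, conditions = cm$conditions,
    time_points = cm$time_points, values = cm$values,
    annotations = annotations, replicate_sets = cm$replicate_sets,
    replicate_variance = cm$replicate_variance)
}

#' Write a dataset in the native CSV dialect
#'
#' Inverse of [read_csv_native()]: the write/read round trip reproduces gene
#' ids, conditions, time points, values and the missing mask exactly
#' (missing values become empty cells, numbers are printed with full
#' round-trip precision).
#'
#' @param dataset An `ExpressionDataset`.
#' @param path Output file path.
#' @export
write_csv_native <- function(dataset, path) {
  cols <- list(gene_id = dataset$gene_ids)
  if (!is.null(dataset$annotations)) cols$annotation <- dataset$annotations
  for (cn in dataset$conditions) {
    tt <- dataset$time_points[[cn]]
    V <- dataset$values[[cn]]
    for (k in seq_along(tt)) {
      h <- paste(cn, sprintf("%.15g", tt[k]), "1", sep = "|")
      x <- sprintf("%.17g", V[, k])
      x[is.na(V[, k])] <- ""
      cols[[h]] <- if (nrow(V)) x else character()
    }
  }
  dt <- data.table::as.data.table(cols)
  data.table::fwrite(dt, path, quote = FALSE)
  invisible(path)
}

#' Read a GDS SOFT dataset file
#'
#' Parses the plain-text GDS SOFT layout: a `!dataset_table_begin` /
#' `!dataset_table_end` table with `ID_REF`, `IDENTIFIER` and one column per
#' sample, plus `^SUBSET` blocks whose `time`-typed subsets supply the time
#' value of each sample and whose other subsets (agent, strain, ...) supply
#' condition labels. Unparseable cells and the literal `"null"` become
#' missing values; table row order is preserved as gene order.
#'
#' @param path Path to the SOFT file.
#' @param dataset_id Dataset identifier; defaults to the `^DATASET` name or
#'   the file name.
#' @return An [expression_dataset()].
#' @export
read_soft_gds <- function(path, dataset_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  lo <- tolower(lines)
  beg <- which(startsWith(lo, "!dataset_table_begin"))
  end <- which(startsWith(lo, "!dataset_table_end"))
  if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L) {
    stop("format error: no dataset table found (not a GDS SOFT file?)")
  }
  tab <- lines[(beg + 1L):(end - 1L)]
  header <- strsplit(tab[1], "\t", fixed = TRUE)[[1]]
  body <- tab[-1]
  body <- body[nzchar(body)]
  cells <- strsplit(body, "\t", fixed = TRUE)
  cells <- lapply(cells, function(x) { length(x) <- length(header); x })
  M <- do.call(rbind, cells)
  id_col <- match(TRUE, toupper(header) == "ID_REF", nomatch = 1L)
  ident_col <- which(toupper(header) == "IDENTIFIER")
  sample_cols <- setdiff(seq_along(header), c(id_col, ident_col))

  # subset metadata
  sub_time <- list(); sub_cond <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (startsWith(lines[i], "^SUBSET")) {
      desc <- NA_character_; ids <- character(); type <- NA_character_
      j <- i + 1L
      while (j <= length(lines) && !startsWith(lines[j], "^")) {
        kv <- sub("^!", "", lines[j])
        if (grepl("=", kv, fixed = TRUE)) {
          key <- trimws(sub("=.*$", "", kv))
          val <- trimws(sub("^[^=]*=", "", kv))
          if (key == "subset_description") desc <- val
          if (key == "subset_sample_id") ids <- trimws(strsplit(val, ",")[[1]])
          if (key == "subset_type") type <- val
        }
        j <- j + 1L
      }
      if (identical(tolower(type), "time")) {
        tv <- regmatches(desc, regexpr("-?[0-9]+\\.?[0-9]*", desc))
        tval <- if (length(tv)) as.numeric(tv) else NA_real_
        for (s in ids) sub_time[[s]] <- tval
      } else {
        for (s in ids) if (is.null(sub_cond[[s]])) sub_cond[[s]] <- desc
      }
      i <- j
    } else i <- i + 1L
  }

  samples <- header[sample_cols]
  time <- vapply(samples, function(s) {
    v <- sub_time[[s]]
    if (is.null(v)) NA_real_ else v
  }, numeric(1))
  if (any(is.na(time))) {
    stop("mapping error: sample column(s) not covered by any time subset: ",
         paste(samples[is.na(time)], collapse = ", "))
  }
  cond <- vapply(samples, function(s) {
    v <- sub_cond[[s]]
    if (is.null(v) || is.na(v)) "all" else v
  }, character(1))

  gene_ids <- as.character(M[, id_col])
  annotations <- if (length(ident_col)) as.character(M[, ident_col[1]]) else NULL
  raw <- matrix(parse_cells(M[, sample_cols, drop = FALSE], lenient = TRUE),
                nrow = length(gene_ids))
  cm <- collapse_measurements(raw, cond, time, samples, gene_ids)
  if (is.null(dataset_id)) {
    dsl <- lines[startsWith(lines, "^DATASET")]
    dataset_id <- if (length(dsl)) trimws(sub("^[^=]*=", "", dsl[1])) else basename(path)
  }
  expression_dataset(dataset_id = dataset_id, gene_ids = gene_ids,
                     conditions = cm$conditions, time_points = cm$time_points,
                     values = cm$values, annotations = annotations,
                     replicate_sets = cm$replicate_sets,
                     replicate_variance = cm$replicate_variance)
}

#' MAGE-TAB import placeholder
#'
#' The MAGE-TAB exchange format is acknowledged but not parsed; calling this
#' raises a clear error rather than misparsing the file.
#'
#' @param path Path to a MAGE-TAB file (unused).
#' @export
read_mage_tab <- function(path) {
  stop("format not supported: MAGE-TAB parsing is not implemented")
}
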