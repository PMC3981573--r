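#' Per-value rescaling (log2, log10, cube root)
#'
#' Replaces every expression value elementwise; missing values stay missing;
#' the transform is appended to the dataset's transform log so stored
#' patterns can cite it. Log transforms require strictly positive data; the
#' cube root is odd-symmetric and therefore the option usable on negative
#' (e.g. ratio-subtracted) data.
#'
#' @param dataset An `ExpressionDataset`.
#' @param kind One of `"log2"`, `"log10"`, `"cube_root"`.
#' @return The transformed dataset.
#' @export
apply_per_value <- function(dataset, kind = c("log2", "log10", "cube_root")) {
  kind <- match.arg(kind)
  f <- switch(kind,
              log2 = log2, log10 = log10,
              cube_root = function(v) sign(v) * abs(v)^(1 / 3))
  for (cn in dataset$conditions) {
    V <- dataset$values[[cn]]
    if (kind != "cube_root") {
      bad <- which(!is.na(V) & V <= 0, arr.ind = TRUE)
      if (nrow(bad)) {
        stop("domain error: non-positive value under ", kind, " for gene '",
             dataset$gene_ids[bad[1, 1]], "', condition '", cn, "', time ",
             dataset$time_points[[cn]][bad[1, 2]])
      }
    }
    dataset$values[[cn]] <- f(V)
  }
  dataset$transform_log <- c(dataset$transform_log, kind)
  dataset
}

# TRUE when the dataset is currently on a log scale (per its transform log)
is_log_scaled <- function(dataset) {
  any(dataset$transform_log %in% c("log2", "log10"))
}

#' Rescale every gene to a reference data point or combination
#'
#' On a log-scaled dataset (per the transform log) the per-gene reference
#' value is subtracted, so the reference time point maps to 0; on an unlogged
#' dataset values are divided by the reference (fold change, reference maps
#' to 1). The reference is a time-point label (e.g. `"V10"`), a numeric time
#' value, or a per-gene combination rule: `"error_weighted_mean"`
#' (inverse-replicate-variance weights across the gene's time points, equal
#' weights where variances are unavailable) or `"median"`.
#'
#' @param dataset An `ExpressionDataset`.
#' @param reference Time-point label, numeric time, `"error_weighted_mean"`
#'   or `"median"`.
#' @return The rescaled dataset, with `"rescale_to:<reference>"` appended to
#'   its transform log.
#' @export
apply_reference_rescale <- function(dataset, reference) {
  logged <- is_log_scaled(dataset)
  for (cn in dataset$conditions) {
    V <- dataset$values[[cn]]
    ref <- reference_values(dataset, cn, reference)
    if (logged) {
      dataset$values[[cn]] <- V - ref
    } else {
      ref[!is.na(ref) & ref == 0] <- NA_real_
      dataset$values[[cn]] <- V / ref
    }
  }
  dataset$transform_log <- c(dataset$transform_log,
                             paste0("rescale_to:", as.character(reference)))
  dataset
}

# per-gene reference column for one condition
reference_values <- function(dataset, condition, reference) {
  V <- dataset$values[[condition]]
  if (identical(reference, "median")) {
    return(apply(V, 1, stats::median, na.rm = TRUE))
  }
  if (identical(reference, "error_weighted_mean")) {
    S <- dataset$replicate_variance[[condition]]
    return(vapply(seq_len(nrow(V)), function(i) {
      v <- V[i, ]
      ok <- !is.na(v)
      if (!any(ok)) return(NA_real_)
      w <- if (is.null(S)) rep(NA_real_, length(v)) else 1 / S[i, ]
      # equal-weight fallback when any needed variance is unavailable
      if (any(!is.finite(w[ok]) | w[ok] <= 0)) w <- rep(1, length(v))
      sum(w[ok] * v[ok]) / sum(w[ok])
    }, numeric(1)))
  }
  idx <- resolve_time_point(dataset, condition, reference)
  if (is.na(idx)) {
    stop("lookup error: unknown reference '", reference, "' in condition '",
         condition, "'")
  }
  V[, idx]
}

#' Replay a dataset's transform log from the raw import
#'
#' Rescaling is re-applicable mid-session: rather than inverting transforms,
#' the dataset keeps its raw imported values and the ordered transform log,
#' and any change of rescaling options is realised by replaying the log from
#' raw. `replay_transforms(dataset)` reproduces the current values exactly.
#'
#' @param dataset An `ExpressionDataset`.
#' @param transform_log Log to replay; defaults to the dataset's own.
#' @return A dataset rebuilt from raw values with the log applied.
#' @export
replay_transforms <- function(dataset, transform_log = dataset$transform_log) {
  ds <- dataset
  ds$values <- ds$raw_values
  ds$interpolated <- NULL
  ds$transform_log <- character()
  for (spec in transform_log) {
    if (spec %in% c("log2", "log10", "cube_root")) {
      ds <- apply_per_value(ds, spec)
    } else if (startsWith(spec, "rescale_to:")) {
      ref <- sub("^rescale_to:", "", spec)
      num <- suppressWarnings(as.numeric(ref))
      ds <- apply_reference_rescale(ds, if (!is.na(num)) num else ref)
    } else {
      stop("unknown transform spec: ", spec)
    }
  }
  ds
}
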