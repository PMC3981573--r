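#' Specify a synthetic expression time-course fixture
#'
#' The generator emulates the data regimes the layout and query machinery
#' are meant to reveal: a background of smooth gene-specific trajectories
#' plus measurement noise, with "planted" gene groups carrying a temporal
#' pattern confined to a sub-interval. Background series are Gaussian random
#' walks with a per-gene drift (steps ~ N(drift_g, walk_sd^2), drift_g ~
#' N(0, drift_sd^2)) plus i.i.d. observation noise per replicate; drift
#' gives genes the large, smooth whole-profile differences that dominate
#' full-profile clustering, while per-step changes stay small, so a planted
#' interval reversal stands out to interval queries.
#'
#' @param n_genes Number of genes.
#' @param times Strictly increasing time grid (shared by all conditions).
#' @param conditions Condition labels.
#' @param noise_sd Baseline noise scale: sd of per-replicate observation
#'   noise. Planted effect sizes and query thresholds are expressed as
#'   multiples of this scale.
#' @param replicates Replicates per (condition, time), collapsed by mean.
#' @param walk_sd Random-walk step sd.
#' @param drift_sd Per-gene drift sd (per step).
#' @param missing_rate Fraction of collapsed cells set missing (avoiding
#'   planted genes' interval grid points).
#' @param planted List of planted groups, each a list with `name`, `n`,
#'   `interval` (start and end grid times), `shape` (`"rise_fall"`,
#'   `"early_rise"`, `"upward"`, `"downward"`) and `effect` (peak height as
#'   a multiple of `noise_sd`). Groups are disjoint and planted in the
#'   first condition.
#' @param seed Integer seed; identical seeds give identical datasets.
#' @param dataset_id Dataset identifier.
#' @param time_labels Optional display labels for the grid.
#' @param time_unit Time unit label.
#' @return A `FixtureSpec`.
#' @export
fixture_spec <- function(n_genes, times = 0:9, conditions = "c1",
                         noise_sd = 0.2, replicates = 4L, walk_sd = 0.05,
                         drift_sd = 0.06, missing_rate = 0, planted = list(),
                         seed = 1L, dataset_id = "synthetic",
                         time_labels = NULL, time_unit = "days") {
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  n_planted <- sum(vapply(planted, function(g) as.integer(g$n), integer(1)))
  if (n_planted > n_genes) {
    stop("spec error: planted members (", n_planted, ") exceed n_genes (",
         n_genes, ")")
  }
  for (g in planted) {
    if (!all(g$interval %in% times)) {
      stop("spec error: planted interval must use grid times")
    }
    if (!g$shape %in% c("rise_fall", "early_rise", "upward", "downward")) {
      stop("spec error: unknown profile shape: ", g$shape)
    }
  }
  structure(list(n_genes = as.integer(n_genes), times = times,
                 conditions = as.character(conditions), noise_sd = noise_sd,
                 replicates = as.integer(replicates), walk_sd = walk_sd,
                 drift_sd = drift_sd, missing_rate = missing_rate,
                 planted = planted, seed = as.integer(seed),
                 dataset_id = dataset_id, time_labels = time_labels,
                 time_unit = time_unit),
            class = "FixtureSpec")
}

# profile shape evaluated on the grid, scaled to peak height `peak`
profile_shape <- function(shape, times, interval, peak) {
  s <- interval[1]; e <- interval[2]
  out <- numeric(length(times))
  inside <- times >= s & times <= e
  if (shape == "rise_fall") {
    mid <- (s + e) / 2
    out[inside] <- peak * (1 - abs(times[inside] - mid) / ((e - s) / 2))
  } else {
    ramp <- (times - s) / (e - s)
    sgn <- if (shape == "downward") -1 else 1
    out[inside] <- sgn * peak * ramp[inside]
    out[times > e] <- sgn * peak
  }
  out
}

#' Generate a synthetic dataset with planted temporal patterns
#'
#' Deterministic for a given spec (including its seed). Planted genes are
#' background plus the profile shape localized to the interval; missing
#' values are inserted at the stated rate while avoiding the grid points of
#' planted genes' intervals, so the planted signal itself is never censored.
#'
#' @param spec A [fixture_spec()].
#' @return A list with `dataset` (an [expression_dataset()], replicates
#'   already collapsed) and `truth` (planted memberships, intervals, shapes,
#'   effect sizes, and the effect/noise ratio).
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "FixtureSpec"))
  set.seed(spec$seed)
  n <- spec$n_genes
  tt <- spec$times
  Tn <- length(tt)
  gene_ids <- sprintf("gene_%05d", seq_len(n))

  # assign planted members: disjoint, deterministic under the seed
  pool <- sample.int(n)
  truth_groups <- list()
  signal <- matrix(0, nrow = n, ncol = Tn)
  off <- 0L
  for (g in spec$planted) {
    members <- sort(pool[(off + 1L):(off + g$n)])
    off <- off + g$n
    peak <- g$effect * spec$noise_sd
    prof <- profile_shape(g$shape, tt, g$interval, peak)
    signal[members, ] <- signal[members, ] +
      matrix(prof, nrow = length(members), ncol = Tn, byrow = TRUE)
    truth_groups[[g$name]] <- list(name = g$name,
                                   members = gene_ids[members],
                                   interval = g$interval, shape = g$shape,
                                   effect = g$effect,
                                   condition = spec$conditions[1])
  }

  cum <- upper.tri(matrix(0, Tn - 1L, Tn - 1L), diag = TRUE) * 1
  values <- list(); rvar <- list(); rsets <- list()
  for (ci in seq_along(spec$conditions)) {
    cn <- spec$conditions[ci]
    drift <- stats::rnorm(n, 0, spec$drift_sd)
    steps <- matrix(stats::rnorm(n * (Tn - 1L), mean = drift, sd = spec$walk_sd),
                    nrow = n)
    base <- cbind(0, steps %*% cum)
    if (ci == 1L) base <- base + signal
    reps <- array(stats::rnorm(n * Tn * spec$replicates, 0, spec$noise_sd),
                  dim = c(n, Tn, spec$replicates))
    obs <- sweep(reps, c(1, 2), base, "+")
    V <- rowMeans(obs, dims = 2L)
    S <- if (spec$replicates > 1L) {
      dev <- obs - array(V, dim = dim(obs))
      rowSums(dev^2, dims = 2L) / (spec$replicates - 1L)
    } else NULL
    rownames(V) <- gene_ids
    values[[cn]] <- V
    rvar[[cn]] <- S
    rsets[[cn]] <- lapply(seq_len(Tn), function(k)
      sprintf("%s_t%g_r%d", cn, tt[k], seq_len(spec$replicates)))
  }

  # missing values, avoiding planted genes' interval grid points
  if (spec$missing_rate > 0) {
    protected <- matrix(FALSE, nrow = n, ncol = Tn)
    for (g in truth_groups) {
      rows <- match(g$members, gene_ids)
      cols <- which(tt >= g$interval[1] & tt <= g$interval[2])
      protected[rows, cols] <- TRUE
    }
    for (cn in spec$conditions) {
      eligible <- which(!protected)
      k <- round(spec$missing_rate * n * Tn)
      drop <- sample(eligible, min(k, length(eligible)))
      V <- values[[cn]]
      V[drop] <- NA_real_
      values[[cn]] <- V
    }
  }

  ds <- expression_dataset(
    dataset_id = spec$dataset_id, gene_ids = gene_ids,
    conditions = spec$conditions,
    time_points = stats::setNames(rep(list(tt), length(spec$conditions)),
                                  spec$conditions),
    values = values,
    time_labels = if (!is.null(spec$time_labels))
      stats::setNames(rep(list(spec$time_labels), length(spec$conditions)),
                      spec$conditions) else NULL,
    time_unit = spec$time_unit,
    replicate_sets = rsets, replicate_variance = rvar)
  list(dataset = ds,
       truth = list(groups = truth_groups, seed = spec$seed,
                    noise_sd = spec$noise_sd,
                    effect_noise_ratio = vapply(spec$planted, function(g)
                      g$effect, numeric(1))))
}

#' Ready-made fixture specs emulating published study shapes
#'
#' Two canonical regimes: `mammary17` — 8,500 genes over 17 time points
#' spanning four developmental stages (virgin days 10 and 12; pregnancy days
#' 1, 2, 3, 8.5, 12.5, 14.5, 17.5; lactation days 1, 3, 7; involution days
#' 1, 2, 3, 4, 20) whose repeating per-stage day values are mapped onto one
#' strictly increasing pseudo-time axis with stage-prefixed labels; and
#' `osteoblast7` — 20,000 genes over 7 time points (days 4, 5, 6, 8, 16, 25,
#' 30) under two conditions (growth-factor-exposed vs control), with planted
#' "early rising", "downward" and "upward" groups.
#'
#' @return Named list of [fixture_spec()]s.
#' @export
paper_shapes <- function() {
  mam_days <- list(V = c(10, 12), P = c(1, 2, 3, 8.5, 12.5, 14.5, 17.5),
                   L = c(1, 3, 7), I = c(1, 2, 3, 4, 20))
  times <- c(); labels <- c(); offset <- 0
  for (stage in names(mam_days)) {
    d <- mam_days[[stage]]
    times <- c(times, offset + d)
    labels <- c(labels, paste0(stage, vapply(d, as.character, "")))
    offset <- offset + max(d)
  }
  mammary <- fixture_spec(
    n_genes = 8500L, times = times, conditions = "mammary",
    time_labels = labels, time_unit = "pseudo-days", seed = 170L,
    dataset_id = "mammary17",
    planted = list(list(name = "interval_swing", n = 30L,
                        interval = c(times[3], times[5]),
                        shape = "rise_fall", effect = 6)))
  osteo_times <- c(4, 5, 6, 8, 16, 25, 30)
  osteo <- fixture_spec(
    n_genes = 20000L, times = osteo_times,
    conditions = c("growth_factor", "control"), seed = 3792L,
    dataset_id = "osteoblast7", time_unit = "days",
    planted = list(
      list(name = "early_rising", n = 40L, interval = c(6, 8),
           shape = "early_rise", effect = 6),
      list(name = "downward", n = 40L, interval = c(16, 30),
           shape = "downward", effect = 6),
      list(name = "upward", n = 40L, interval = c(16, 30),
           shape = "upward", effect = 6)))
  list(mammary17 = mammary, osteoblast7 = osteo)
}
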