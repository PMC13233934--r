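# Sequence detection.
#
# Rates are thresholded into pseudo-spikes (x, y, t events); events are
# density-clustered in space-time; each cluster is a spatio-temporal activity
# sequence (STAS).  Because the grid is a torus, clustering runs twice --
# once on raw coordinates and once with both spatial axes shifted by
# nrows/2 -- and clusters sharing events are merged, so sequences that wrap
# around the seam are recovered whole.

#' Sequence-detection parameters
#'
#' @param theta rate threshold for pseudo-spike emission (default 0.4).
#' @param eps density-clustering neighborhood radius in the mixed
#'   (grid-point, ms) space (default 4).
#' @param min_samples minimum neighborhood size for a core point (default 50).
#' @param min_extent minimum spatial traverse of a kept sequence, as the
#'   maximum pairwise toroidal distance between its events (default 8 grid
#'   points); stationary bumps are removed by this filter.
#' @param time_scale multiplier applied to the time axis before clustering
#'   (default 1: time enters in raw ms).
#' @return a `stas_detection` list.
#' @export
detection_params <- function(theta = 0.4, eps = 4, min_samples = 50,
                             min_extent = 8, time_scale = 1) {
  if (theta <= 0 || theta >= 1) stop("`theta` must be in (0, 1)")
  if (eps <= 0) stop("`eps` must be > 0")
  if (min_samples < 1) stop("`min_samples` must be >= 1")
  if (min_extent < 0) stop("`min_extent` must be >= 0")
  structure(list(theta = theta, eps = eps,
                 min_samples = as.integer(min_samples),
                 min_extent = min_extent, time_scale = time_scale),
            class = "stas_detection")
}

#' Detection spot
#'
#' A labeled disk (default radius 2) used to register which sequences cross a
#' location: a sequence crosses the spot if at least one of its participating
#' neurons lies inside the disk.
#'
#' @param label character spot name (e.g. `"pre"`, `"M"`, `"B1"`).
#' @param center 2D spot center.
#' @param radius disk radius in grid points (default 2).
#' @return a `stas_spot` list.
#' @export
detection_spot <- function(label, center, radius = 2) {
  if (radius <= 0) stop("`radius` must be > 0")
  structure(list(label = label, center = center, radius = radius),
            class = "stas_spot")
}

#' Threshold a rate trace into pseudo-spikes
#'
#' Emits one event per (neuron, time step) whose rate is at least `theta`
#' (inclusive threshold).  Only excitatory neurons are considered: they carry
#' the integer-lattice coordinates on which sequences are defined.
#'
#' @param trace a [simulate_rates()] trace.
#' @param theta rate threshold (default 0.4).
#' @return `stas_cloud`: data.frame with columns `x`, `y`, `t` (ms),
#'   `neuron`; attribute `nrows`.
#' @export
threshold_to_pseudospikes <- function(trace, theta = 0.4) {
  nrows <- trace$nrows
  n_exc <- nrows * nrows
  rates <- trace$rates[seq_len(min(n_exc, nrow(trace$rates))), , drop = FALSE]
  hits <- which(rates >= theta, arr.ind = TRUE)
  cloud <- data.frame(
    x = as.numeric((hits[, 1] - 1L) %% nrows),
    y = as.numeric((hits[, 1] - 1L) %/% nrows),
    t = trace$time[hits[, 2]],
    neuron = as.integer(hits[, 1])
  )
  cloud <- cloud[order(cloud$t, cloud$neuron), , drop = FALSE]
  rownames(cloud) <- NULL
  attr(cloud, "nrows") <- nrows
  class(cloud) <- c("stas_cloud", "data.frame")
  cloud
}

new_sequence <- function(id, events, nrows) {
  xy <- unique(events[, c("x", "y"), drop = FALSE])
  extent <- cpp_max_pairwise_toroidal(as.matrix(xy), nrows)
  structure(
    list(id = id, events = events, neurons = sort(unique(events$neuron)),
         t_start = min(events$t), t_end = max(events$t),
         duration = max(events$t) - min(events$t), extent = extent),
    class = "stas_sequence"
  )
}

#' @method print stas_sequence
#' @export
print.stas_sequence <- function(x, ...) {
  cat("stas_sequence #", x$id, ": ", nrow(x$events), " events, ",
      length(x$neurons), " neurons, t = [", x$t_start, ", ", x$t_end,
      "] ms, extent ", round(x$extent, 2), "\n", sep = "")
  invisible(x)
}

#' Torus-aware density clustering of pseudo-spikes
#'
#' Runs Euclidean density clustering (DBSCAN; eps / min_samples from
#' `params`) on `(x, y, time_scale * t)`, then again with both spatial axes
#' shifted by `nrows/2` (mod `nrows`), and merges clusters from the two runs
#' that share at least one event (transitively).  Events that are noise in
#' both runs are discarded.  Each merged cluster is returned as one sequence.
#'
#' @param cloud a [threshold_to_pseudospikes()] cloud.
#' @param params a [detection_params()] object.
#' @param geometry the matching [build_grid()] object.
#' @return list of `stas_sequence` (unfiltered; see [filter_sequences()]).
#' @export
cluster_toroidal <- function(cloud, params = detection_params(), geometry) {
  nrows <- geometry$nrows
  if (!nrow(cloud)) return(list())
  ts <- cloud$t * params$time_scale
  lab1 <- cpp_dbscan(cbind(cloud$x, cloud$y, ts), params$eps, params$min_samples)
  xs <- (cloud$x + nrows / 2) %% nrows
  ys <- (cloud$y + nrows / 2) %% nrows
  lab2 <- cpp_dbscan(cbind(xs, ys, ts), params$eps, params$min_samples)

  k1 <- max(lab1, 0L)
  k2 <- max(lab2, 0L)
  if (k1 + k2 == 0L) return(list())
  # union-find over cluster nodes of the two runs
  parent <- seq_len(k1 + k2)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  both <- which(lab1 > 0L & lab2 > 0L)
  for (e in both) {
    a <- find(lab1[e]); b <- find(k1 + lab2[e])
    if (a != b) parent[b] <- a
  }
  node <- ifelse(lab1 > 0L, lab1, ifelse(lab2 > 0L, k1 + lab2, NA_integer_))
  keep <- !is.na(node)
  comp <- vapply(node[keep], find, integer(1))
  comp <- match(comp, sort(unique(comp)))
  ev <- cloud[keep, , drop = FALSE]
  lapply(seq_len(max(comp)), function(cid) {
    new_sequence(cid, ev[comp == cid, , drop = FALSE], nrows)
  })
}

#' Remove sequences that do not traverse space
#'
#' Keeps sequences whose spatial extent (maximum pairwise toroidal distance
#' between event coordinates) is at least `min_extent`.  This drops very
#' short sequences and stationary bumps.
#'
#' @param sequences list from [cluster_toroidal()].
#' @param params a [detection_params()] object.
#' @param geometry matching [build_grid()] object (unused except for API
#'   symmetry; extents are stored on the sequences).
#' @return filtered list of `stas_sequence`, ids renumbered.
#' @export
filter_sequences <- function(sequences, params = detection_params(), geometry = NULL) {
  kept <- Filter(function(s) s$extent >= params$min_extent, sequences)
  for (i in seq_along(kept)) kept[[i]]$id <- i
  kept
}

#' Detect sequences in a rate trace
#'
#' Convenience pipeline: threshold, cluster toroidally, filter.
#'
#' @inheritParams threshold_to_pseudospikes
#' @inheritParams cluster_toroidal
#' @return filtered list of `stas_sequence`.
#' @export
detect_sequences <- function(trace, params = detection_params(), geometry) {
  cloud <- threshold_to_pseudospikes(trace, params$theta)
  filter_sequences(cluster_toroidal(cloud, params, geometry), params)
}

#' Static-bump screening
#'
#' Flags runs whose unfiltered clusters contain a saturated stationary
#' cluster: spatial extent below `extent_thresh` but duration of at least
#' `frac` of the simulated time.  Landscapes and patches producing such bumps
#' are excluded from motif analyses.
#'
#' @param sequences unfiltered list from [cluster_toroidal()].
#' @param t_sim simulated duration (ms).
#' @param extent_thresh extent threshold (default 8 grid points).
#' @param frac duration fraction (default 0.9).
#' @return logical flag.
#' @export
is_static_bump_run <- function(sequences, t_sim, extent_thresh = 8, frac = 0.9) {
  any(vapply(sequences, function(s)
    s$extent < extent_thresh && s$duration >= frac * t_sim, logical(1)))
}

#' Sequence landscape
#'
#' Counts, for every excitatory neuron, the number of sequences it
#' participated in.  Peaks of this landscape are the reliable pathways;
#' saddles between peaks mark unreliable (semi-transmissive) links.
#'
#' @param sequences filtered list of `stas_sequence`.
#' @param geometry matching [build_grid()] object.
#' @return `stas_landscape`: list with integer `count` (length `nrows^2`) and
#'   `nrows`.
#' @export
sequence_landscape <- function(sequences, geometry) {
  n_exc <- nrow(geometry$exc_positions)
  count <- integer(n_exc)
  for (s in sequences) count[s$neurons] <- count[s$neurons] + 1L
  structure(list(count = count, nrows = geometry$nrows),
            class = "stas_landscape")
}

#' Spot crossings of sequences
#'
#' For every (sequence, spot) pair: did any participating neuron of the
#' sequence lie within the spot disk, and if so, what is the earliest event
#' time of those in-spot neurons (first crossing time).
#'
#' @param sequences filtered list of `stas_sequence`.
#' @param spots list of [detection_spot()] objects.
#' @param geometry matching [build_grid()] object.
#' @return data.frame with columns `seq_id`, `spot`, `crossed`, `t_first`
#'   (`NA` when not crossed).
#' @export
spot_crossings <- function(sequences, spots, geometry) {
  members <- lapply(spots, function(sp)
    neurons_in_disk(sp$center, sp$radius, geometry, "exc"))
  labels <- vapply(spots, `[[`, character(1), "label")
  rows <- list()
  for (s in sequences) {
    for (k in seq_along(spots)) {
      inside <- s$events$neuron %in% members[[k]]
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = s$id, spot = labels[k], crossed = any(inside),
        t_first = if (any(inside)) min(s$events$t[inside]) else NA_real_
      )
    }
  }
  if (!length(rows))
    return(data.frame(seq_id = integer(), spot = character(),
                      crossed = logical(), t_first = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-run sequence summary
#'
#' @param sequences filtered list of `stas_sequence`.
#' @return data.frame with `count` and mean `duration` (0 sequences -> NA
#'   duration).
#' @export
run_summary <- function(sequences) {
  data.frame(
    count = length(sequences),
    duration = if (length(sequences))
      mean(vapply(sequences, `[[`, numeric(1), "duration")) else NA_real_
  )
}

#' Network-wide effect of a modulation
#'
#' Differences in sequence count and mean duration between matched
#' modulated and baseline runs (same noise seeds), with the standard error
#' of the mean across seeds.
#'
#' @param baseline_runs,modulated_runs data.frames with columns `seed`,
#'   `count`, `duration` (one row per noise realization).
#' @return one-row data.frame: `d_count`, `d_count_sem`, `d_duration`,
#'   `d_duration_sem`, `n_seeds`.
#' @export
network_effect_summary <- function(baseline_runs, modulated_runs) {
  if (nrow(baseline_runs) < 2 || nrow(modulated_runs) < 2)
    stop("need at least 2 runs per condition")
  if (!setequal(baseline_runs$seed, modulated_runs$seed))
    stop("baseline and modulated runs must use matched seed sets")
  b <- baseline_runs[order(baseline_runs$seed), ]
  m <- modulated_runs[order(modulated_runs$seed), ]
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  dc <- m$count - b$count
  dd <- m$duration - b$duration
  data.frame(d_count = mean(dc), d_count_sem = sem(dc),
             d_duration = mean(dd, na.rm = TRUE),
             d_duration_sem = sem(dd[!is.na(dd)]),
             n_seeds = nrow(b))
}

#' Export a sequence catalog as delimited text
#'
#' Writes one row per sequence (id, t_start, t_end, duration, extent, neuron
#' count) and, optionally, the full event table.
#'
#' @param sequences filtered list of `stas_sequence`.
#' @param path output TSV path for the catalog.
#' @param events_path optional TSV path for the event table.
#' @return `path`, invisibly.
#' @export
export_sequences <- function(sequences, path, events_path = NULL) {
  cat_df <- do.call(rbind, lapply(sequences, function(s) data.frame(
    id = s$id, t_start = s$t_start, t_end = s$t_end,
    duration = s$duration, extent = s$extent, n_neurons = length(s$neurons))))
  if (is.null(cat_df))
    cat_df <- data.frame(id = integer(), t_start = numeric(), t_end = numeric(),
                         duration = numeric(), extent = numeric(),
                         n_neurons = integer())
  utils::write.table(cat_df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(events_path)) {
    ev <- do.call(rbind, lapply(sequences, function(s)
      cbind(seq_id = s$id, s$events)))
    if (is.null(ev)) ev <- data.frame(seq_id = integer(), x = numeric(),
                                      y = numeric(), t = numeric(),
                                      neuron = integer())
    utils::write.table(ev, events_path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
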