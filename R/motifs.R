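# Motif quantification.
#
# Motifs (Start, Repeat/Stop, Anti-Repeat, Select, Gate) are characterized by
# how a patch changes the conditional transmission probability between
# detection spots: P(post|pre) is the fraction of sequences crossing `pre`
# that subsequently cross `post` (temporal ordering of first crossings).

spot_label <- function(spot) if (inherits(spot, "stas_spot")) spot$label else spot

#' Pool spot-crossing tables across runs
#'
#' Concatenates per-run [spot_crossings()] tables, prefixing sequence ids
#' with the run index so ids stay unique.
#'
#' @param crossings_list list of crossing data.frames (one per noise seed).
#' @return single pooled data.frame with a `run` column.
#' @export
pool_crossings <- function(crossings_list) {
  out <- do.call(rbind, lapply(seq_along(crossings_list), function(i) {
    cr <- crossings_list[[i]]
    if (!nrow(cr)) return(NULL)
    cr$run <- i
    cr$seq_id <- paste0(i, ":", cr$seq_id)
    cr
  }))
  if (is.null(out))
    out <- data.frame(seq_id = character(), spot = character(),
                      crossed = logical(), t_first = numeric(), run = integer())
  out
}

#' Conditional transmission probabilities between two spots
#'
#' Counts, over a (pooled) crossing table: `n_pre` and `n_post` sequences
#' crossing each spot, `n_both` crossing both, and `n_ordered_both` crossing
#' both with the first crossing at `pre` no later than at `post`.  Then
#' `P(post|pre) = n_ordered_both / n_pre` and
#' `P(pre|post) = n_ordered_both / n_post`.  Undefined ratios (zero
#' denominator) are reported as `NA`, never 0.
#'
#' @param crossings a [spot_crossings()] or [pool_crossings()] data.frame.
#' @param pre_spot,post_spot spot labels or [detection_spot()] objects.
#' @return `stas_transmission`: one-row data.frame with the counts and both
#'   conditional probabilities.
#' @export
transmission <- function(crossings, pre_spot, post_spot) {
  pre <- spot_label(pre_spot); post <- spot_label(post_spot)
  a <- crossings[crossings$spot == pre, ]
  b <- crossings[crossings$spot == post, ]
  tb <- merge(a[, c("seq_id", "crossed", "t_first")],
              b[, c("seq_id", "crossed", "t_first")],
              by = "seq_id", suffixes = c("_pre", "_post"))
  n_pre <- sum(tb$crossed_pre)
  n_post <- sum(tb$crossed_post)
  both <- tb$crossed_pre & tb$crossed_post
  n_both <- sum(both)
  n_ordered <- sum(both & tb$t_first_pre <= tb$t_first_post, na.rm = TRUE)
  out <- data.frame(
    pre = pre, post = post,
    n_pre = n_pre, n_post = n_post, n_both = n_both,
    n_ordered_both = n_ordered,
    p_post_given_pre = if (n_pre > 0) n_ordered / n_pre else NA_real_,
    p_pre_given_post = if (n_post > 0) n_ordered / n_post else NA_real_
  )
  class(out) <- c("stas_transmission", "data.frame")
  out
}

#' Per-run transmission estimates
#'
#' Computes [transmission()] separately for each run and returns the mean of
#' the per-run ratios alongside, as a cross-check of the pooled estimator
#' (pooling is more robust when per-run denominators are small).
#'
#' @param crossings_list list of per-run crossing data.frames.
#' @param pre_spot,post_spot as in [transmission()].
#' @return list with `per_run` (data.frame) and `mean_p_post_given_pre`,
#'   `mean_p_pre_given_post` (means over runs with defined ratios).
#' @export
transmission_by_run <- function(crossings_list, pre_spot, post_spot) {
  per <- do.call(rbind, lapply(crossings_list, transmission,
                               pre_spot = pre_spot, post_spot = post_spot))
  list(per_run = per,
       mean_p_post_given_pre = mean(per$p_post_given_pre, na.rm = TRUE),
       mean_p_pre_given_post = mean(per$p_pre_given_post, na.rm = TRUE))
}

#' Branch-alignment window
#'
#' @param t_window alignment window in ms (default 200).
#' @param spots named list of [detection_spot()]s `M`, `B1`, `B2`.
#' @return a `stas_window` list.
#' @export
branch_window <- function(t_window = 200, spots) {
  if (t_window <= 0) stop("`t_window` must be > 0")
  if (!all(c("M", "B1", "B2") %in% names(spots)))
    stop("`spots` must name M, B1 and B2")
  structure(list(t_window = t_window, spots = spots), class = "stas_window")
}

#' Group sequences into branch episodes and classify them
#'
#' Sequences whose first crossings at the branch spots `B1`, `B2` and the
#' main spot `M` fall within `t_window` of each other form an episode.  The
#' earliest branch crossing opens an episode; crossings within `t_window`
#' of the anchor join it; episodes are disjoint.  Classification:
#' \describe{
#'   \item{cooperation}{one (merged) sequence crosses `B1`, `B2` and `M`}
#'   \item{competition}{distinct sequences cross `B1` and `B2` within the
#'     window and at most one reaches `M`}
#'   \item{single}{only one branch is active}
#'   \item{none}{no branch crossing in the episode}
#' }
#' For each episode, per-ms active-neuron counts are binned per branch
#' region (events assigned to the nearest of the three spots).  For
#' cooperation episodes `merge_time` is the first millisecond at which both
#' branch clouds are present and within `eps` of each other
#' (density-connected); for competition, `max_competition_time` is the time
#' of minimum summed branch activity between the two branch crossings.
#'
#' @param sequences filtered list of `stas_sequence` from one run.
#' @param window a [branch_window()] object.
#' @param crossings the run's [spot_crossings()] table for `M`, `B1`, `B2`.
#' @param geometry matching [build_grid()] object.
#' @param eps density-connection radius for the merge time (default 4).
#' @return list of `stas_episode` records.
#' @export
branch_episodes <- function(sequences, window, crossings, geometry, eps = 4) {
  spots <- window$spots
  cr <- crossings[crossings$crossed, , drop = FALSE]
  if (!nrow(cr)) return(list())
  cr <- cr[order(cr$t_first), , drop = FALSE]
  # disjoint episodes anchored at the earliest remaining crossing
  episode_id <- integer(nrow(cr))
  eid <- 0L; anchor <- -Inf
  for (i in seq_len(nrow(cr))) {
    if (cr$t_first[i] > anchor + window$t_window) {
      eid <- eid + 1L
      anchor <- cr$t_first[i]
    }
    episode_id[i] <- eid
  }
  seq_by_id <- stats::setNames(sequences,
                               vapply(sequences, `[[`, numeric(1), "id"))
  centers <- rbind(spots$M$center, spots$B1$center, spots$B2$center)
  region_names <- c("M", "B1", "B2")

  lapply(split(seq_len(nrow(cr)), episode_id), function(idx) {
    sub <- cr[idx, , drop = FALSE]
    sids <- unique(sub$seq_id)
    crossed_by <- function(sp) unique(sub$seq_id[sub$spot == sp])
    b1 <- crossed_by("B1"); b2 <- crossed_by("B2"); m <- crossed_by("M")
    coop_seq <- intersect(intersect(b1, b2), m)
    cls <- if (length(coop_seq)) "cooperation"
      else if (length(b1) && length(b2)) "competition"
      else if (xor(length(b1) > 0, length(b2) > 0)) "single"
      else "none"

    # per-ms active-neuron counts per branch region
    ev <- do.call(rbind, lapply(sids, function(s) seq_by_id[[as.character(s)]]$events))
    counts <- NULL
    if (!is.null(ev) && nrow(ev)) {
      d <- sapply(seq_len(3), function(k)
        toroidal_distance(as.matrix(ev[, c("x", "y")]),
                          matrix(centers[k, ], nrow(ev), 2, byrow = TRUE),
                          geometry$nrows))
      region <- region_names[max.col(-d)]
      tt <- sort(unique(ev$t))
      counts <- sapply(region_names, function(rg)
        vapply(tt, function(ti) sum(ev$t == ti & region == rg), integer(1)))
      counts <- cbind(t = tt, as.data.frame(counts))
    }

    merge_time <- NA_real_
    if (cls == "cooperation") {
      s <- seq_by_id[[as.character(coop_seq[1])]]
      evs <- s$events
      d1 <- toroidal_distance(as.matrix(evs[, c("x", "y")]),
                              matrix(spots$B1$center, nrow(evs), 2, byrow = TRUE),
                              geometry$nrows)
      d2 <- toroidal_distance(as.matrix(evs[, c("x", "y")]),
                              matrix(spots$B2$center, nrow(evs), 2, byrow = TRUE),
                              geometry$nrows)
      side <- ifelse(d1 <= d2, "B1", "B2")
      for (ti in sort(unique(evs$t))) {
        i1 <- evs$t == ti & side == "B1"; i2 <- evs$t == ti & side == "B2"
        if (any(i1) && any(i2)) {
          gap <- min(as.vector(outer(seq_len(sum(i1)), seq_len(sum(i2)),
            Vectorize(function(a, b) toroidal_distance(
              c(evs$x[i1][a], evs$y[i1][a]),
              c(evs$x[i2][b], evs$y[i2][b]), geometry$nrows)))))
          if (gap <= eps) { merge_time <- ti; break }
        }
      }
    }

    max_comp_time <- NA_real_
    if (cls == "competition" && !is.null(counts)) {
      tb1 <- min(sub$t_first[sub$spot == "B1"])
      tb2 <- min(sub$t_first[sub$spot == "B2"])
      mid <- counts$t >= min(tb1, tb2) & counts$t <= max(tb1, tb2)
      if (any(mid)) {
        tot <- counts$B1[mid] + counts$B2[mid]
        max_comp_time <- counts$t[mid][which.min(tot)]
      }
    }

    structure(list(sequences = sids, classification = cls,
                   counts = counts, merge_time = merge_time,
                   max_competition_time = max_comp_time,
                   t_anchor = min(sub$t_first)),
              class = "stas_episode")
  })
}

#' Side-by-side motif effect report
#'
#' Combines baseline and patch [transmission()] rows into one table with
#' effect sizes and direction-of-effect flags.
#'
#' @param baseline_stats,patch_stats `stas_transmission` rows (or data.frames
#'   of several, matched by `pre`/`post`).
#' @return data.frame with baseline and patch counts/probabilities, deltas,
#'   and `direction` (`"increase"`, `"decrease"`, `"none"`) per metric.
#' @export
motif_report <- function(baseline_stats, patch_stats) {
  m <- merge(as.data.frame(baseline_stats), as.data.frame(patch_stats),
             by = c("pre", "post"), suffixes = c("_baseline", "_patch"))
  dirn <- function(d) ifelse(is.na(d) | d == 0, "none",
                             ifelse(d > 0, "increase", "decrease"))
  m$d_p_post_given_pre <- m$p_post_given_pre_patch - m$p_post_given_pre_baseline
  m$d_p_pre_given_post <- m$p_pre_given_post_patch - m$p_pre_given_post_baseline
  m$d_n_pre <- m$n_pre_patch - m$n_pre_baseline
  m$direction_p_post_given_pre <- dirn(m$d_p_post_given_pre)
  m$direction_p_pre_given_post <- dirn(m$d_p_pre_given_post)
  m$direction_n_pre <- dirn(m$d_n_pre)
  m
}
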