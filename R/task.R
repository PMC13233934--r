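# Task-specific networks.
#
# Instead of sampling preferred directions from gradient noise, a direction
# field is compiled from a drawn circuit: pathways (polylines with a width)
# along which neurons point down the local tangent plus a small inward
# component that keeps activity on the path; source cones, regions of
# converging directions whose in-degree hotspot nucleates sequences; and
# terminal fans where a pathway's directions diverge so arriving sequences
# dissipate instead of piling up.  Neurons far from the task structure get
# no preferred direction (zero kernel shift).  Motif patches (Start, Gate,
# Repeat, Select) placed on the circuit then control how sequences are
# routed, up to a context-reversal task.

#' Pathway specification
#'
#' A pathway is a polyline corridor: neurons within `width` of the line
#' point along the local tangent (toward the next waypoint), bent toward the
#' centerline with strength `attract` so traveling activity is guided.  With
#' `fan = TRUE` the last `fan_length` grid points beyond the final waypoint
#' diverge outward, letting sequences terminate gracefully.
#'
#' @param polyline ordered matrix of 2D waypoints (>= 2 rows, grid
#'   coordinates).
#' @param width half-width of the corridor in grid points (> 0).
#' @param attract inward-bend strength at the corridor edge (default 1.2;
#'   0 gives pure tangents).
#' @param fan diverge directions past the final waypoint (default `TRUE`).
#' @param fan_length length of the fan region in grid points (default 3).
#' @return a `stas_pathway` list.
#' @export
pathway_spec <- function(polyline, width = 4, attract = 1.2, fan = TRUE,
                         fan_length = 3) {
  polyline <- rbind(polyline)
  if (nrow(polyline) < 2) stop("polyline needs at least 2 waypoints")
  if (width <= 0) stop("`width` must be > 0")
  structure(list(polyline = polyline, width = width, attract = attract,
                 fan = fan, fan_length = fan_length),
            class = "stas_pathway")
}

#' Source-cone specification
#'
#' A region behind a pathway entrance whose neurons all point toward the
#' `apex` (the pathway's first waypoint).  The resulting convergence of
#' shifted kernels creates an in-degree hotspot at the apex where the noise
#' drive nucleates sequences, which then travel down the pathway.
#'
#' @param apex 2D focus point (usually a pathway's first waypoint).
#' @param direction_angle angle (radians) of the outgoing pathway; the cone
#'   extends opposite to it.
#' @param length cone depth behind the apex (default 8 grid points).
#' @param halfwidth cone half-height transverse to the direction (default 10).
#' @return a `stas_source` list.
#' @export
source_spec <- function(apex, direction_angle, length = 8, halfwidth = 10) {
  structure(list(apex = apex, direction_angle = direction_angle,
                 length = length, halfwidth = halfwidth),
            class = "stas_source")
}

#' Task specification
#'
#' @param pathways named list of [pathway_spec()]s (e.g. signal, main, left,
#'   right).
#' @param sources named list of [source_spec()]s (sequence nucleation zones).
#' @param motif_patches named list of [make_patch()] objects (e.g. start,
#'   gate, repeat, select_L, select_R).
#' @param spots named list of [detection_spot()]s (e.g. S, M1, M2, L, R).
#' @param contexts named list of character vectors: which motif patches are
#'   active per context; must contain `baseline` (usually empty).
#' @return a `stas_task` list.
#' @export
task_spec <- function(pathways, sources = list(), motif_patches = list(),
                      spots = list(), contexts = list(baseline = character(0))) {
  if (!"baseline" %in% names(contexts))
    contexts <- c(list(baseline = character(0)), contexts)
  bad <- setdiff(unlist(contexts), names(motif_patches))
  if (length(bad)) stop("contexts reference unknown patches: ",
                        paste(bad, collapse = ", "))
  structure(list(pathways = pathways, sources = sources,
                 motif_patches = motif_patches,
                 spots = spots, contexts = contexts),
            class = "stas_task")
}

# per-segment frame: signed lateral offset u, along-path parameter t in
# [0, 1], for points unwrapped around the segment midpoint
segment_frame <- function(pts, a, b, nrows) {
  mid <- (a + b) / 2
  q <- matrix(mid, nrow(pts), 2, byrow = TRUE) +
    toroidal_delta(matrix(mid, nrow(pts), 2, byrow = TRUE), pts, nrows)
  v <- b - a
  len <- sqrt(sum(v^2))
  t_hat <- v / len
  n_hat <- c(-t_hat[2], t_hat[1])
  rel_x <- q[, 1] - a[1]; rel_y <- q[, 2] - a[2]
  list(t = (rel_x * t_hat[1] + rel_y * t_hat[2]) / len,
       u = rel_x * n_hat[1] + rel_y * n_hat[2],
       along = rel_x * t_hat[1] + rel_y * t_hat[2],
       len = len, t_hat = t_hat, n_hat = n_hat)
}

#' Compile a direction field from a task circuit
#'
#' Neurons inside a pathway corridor get a preferred direction along the
#' local tangent bent toward the centerline (`attract`); where corridors
#' overlap (junctions), contributions are blended with inverse-distance
#' weights.  Fanned pathway ends diverge.  Neurons inside a source cone (and
#' on no pathway) point at the cone apex.  All remaining neurons have no
#' preferred direction: their kernel shift is zero, not a random direction.
#'
#' @param task a [task_spec()] object.
#' @param geometry a [build_grid()] object.
#' @return a `stas_field` with `phi` and `has_direction` per excitatory
#'   neuron.
#' @export
compile_task_field <- function(task, geometry) {
  pos <- geometry$exc_positions
  nrows <- geometry$nrows
  n <- nrow(pos)
  sum_sin <- numeric(n); sum_cos <- numeric(n)
  on_path <- logical(n)

  add_dir <- function(idx, angle, weight) {
    sum_sin[idx] <<- sum_sin[idx] + weight * sin(angle)
    sum_cos[idx] <<- sum_cos[idx] + weight * cos(angle)
    on_path[idx] <<- TRUE
  }

  for (pw in task$pathways) {
    pl <- pw$polyline
    for (k in seq_len(nrow(pl) - 1)) {
      fr <- segment_frame(pos, pl[k, ], pl[k + 1, ], nrows)
      inside <- abs(fr$u) <= pw$width & fr$t >= 0 & fr$t <= 1
      if (any(inside)) {
        bend <- -sign(fr$u[inside]) * pmin(abs(fr$u[inside]) / 2, 1) * pw$attract
        vx <- fr$t_hat[1] + bend * fr$n_hat[1]
        vy <- fr$t_hat[2] + bend * fr$n_hat[2]
        add_dir(which(inside), atan2(vy, vx), 1 / (abs(fr$u[inside]) + 0.5))
      }
      last <- k == nrow(pl) - 1
      if (last && pw$fan) {
        beyond <- abs(fr$u) <= pw$width & fr$along > fr$len &
          fr$along <= fr$len + pw$fan_length
        if (any(beyond)) {
          spread <- sign(fr$u[beyond]) * 0.8
          vx <- fr$t_hat[1] + spread * fr$n_hat[1]
          vy <- fr$t_hat[2] + spread * fr$n_hat[2]
          add_dir(which(beyond), atan2(vy, vx), 1 / (abs(fr$u[beyond]) + 0.5))
        }
      }
    }
  }

  # sources claim neurons on no pathway; overlapping cones blend
  # symmetrically (direction vectors summed with inverse-distance weights)
  off_path <- !on_path
  src_sin <- numeric(n); src_cos <- numeric(n); in_src <- logical(n)
  for (src in task$sources) {
    dvec <- c(cos(src$direction_angle), sin(src$direction_angle))
    nvec <- c(-dvec[2], dvec[1])
    rel <- toroidal_delta(matrix(src$apex, n, 2, byrow = TRUE), pos, nrows)
    behind <- -(rel[, 1] * dvec[1] + rel[, 2] * dvec[2])
    lat <- rel[, 1] * nvec[1] + rel[, 2] * nvec[2]
    inside <- behind > 0 & behind <= src$length & abs(lat) <= src$halfwidth &
      off_path
    if (any(inside)) {
      toward <- atan2(-rel[inside, 2], -rel[inside, 1])
      wgt <- 1 / (sqrt(rowSums(rel[inside, , drop = FALSE]^2)) + 0.5)
      src_sin[inside] <- src_sin[inside] + wgt * sin(toward)
      src_cos[inside] <- src_cos[inside] + wgt * cos(toward)
      in_src[inside] <- TRUE
    }
  }
  sum_sin[in_src] <- src_sin[in_src]
  sum_cos[in_src] <- src_cos[in_src]
  on_path <- on_path | in_src
  phi <- ifelse(on_path, atan2(sum_sin, sum_cos) %% (2 * pi), 0)

  structure(list(phi = phi, has_direction = on_path,
                 noise_cells = NA_integer_, seed = NA_integer_),
            class = "stas_field")
}

#' Run a task context and tabulate routing
#'
#' Applies the context's motif patches to the connectome, simulates
#' `config$n_seeds` noise realizations, detects sequences, and tabulates
#' spot crossings and the transitions from the signal spot `S` to every
#' other spot (including the `L`/`R` read-outs).
#'
#' @param connectome connectome built from the compiled task field.
#' @param task a [task_spec()] object.
#' @param context name of a context in `task$contexts`.
#' @param neuron a [neuron_params()] object.
#' @param noise_template a [noise_params()] object; its seed is replaced per
#'   run by a stream derived from `master_seed`.
#' @param config a [sim_config()] object (`n_seeds` realizations).
#' @param detection a [detection_params()] object.
#' @param master_seed integer master seed for the per-run noise streams.
#'   Matched across contexts, so conditions differ only in the applied
#'   patches.
#' @return list with `routing` (data.frame of P(target|S) per target spot),
#'   `crossings` (pooled), `run_summaries`, and `context`.
#' @export
run_context <- function(connectome, task, context = "baseline",
                        neuron = neuron_params(),
                        noise_template = noise_params(),
                        config = sim_config(), detection = detection_params(),
                        master_seed = 1L) {
  if (!context %in% names(task$contexts))
    stop("unknown context: ", context)
  conn <- connectome
  for (pname in task$contexts[[context]])
    conn <- apply_patch(conn, task$motif_patches[[pname]])
  geometry <- conn$geometry
  spots <- unname(task$spots)

  crossings <- vector("list", config$n_seeds)
  summaries <- vector("list", config$n_seeds)
  for (s in seq_len(config$n_seeds)) {
    noise <- noise_template
    noise$seed <- derive_seed(master_seed, "task-noise", s)
    trace <- simulate_rates(conn, neuron, noise, config)
    seqs <- detect_sequences(trace, detection, geometry)
    crossings[[s]] <- spot_crossings(seqs, spots, geometry)
    summaries[[s]] <- cbind(seed = s, run_summary(seqs))
  }
  pooled <- pool_crossings(crossings)
  targets <- setdiff(names(task$spots), "S")
  routing <- do.call(rbind, lapply(targets, function(tg) {
    tr <- transmission(pooled, "S", tg)
    data.frame(target = tg, n_S = tr$n_pre, n_target = tr$n_post,
               n_ordered = tr$n_ordered_both,
               p_target_given_S = tr$p_post_given_pre)
  }))
  list(routing = routing, crossings = pooled,
       run_summaries = do.call(rbind, summaries), context = context)
}
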