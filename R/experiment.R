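# Reproducible experiment runner.
#
# One config drives build -> simulate -> detect -> analyze.  Every source of
# randomness gets a named stream derived from the master seed (connectivity,
# direction field, patch selection, one noise stream per run), so any
# artifact is reproducible from the config alone.  Completed stages are
# persisted under the run directory keyed by a config hash and skipped on
# rerun.

config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Default experiment configuration
#'
#' All defaults equal the reference network values (rescaled via
#' [table1_defaults()] when `nrows != 100`).
#'
#' @param nrows grid side (default 100).
#' @param noise_cells gradient-noise cells per side (default `nrows %/% 10`).
#' @param master_seed master seed from which all named streams are derived.
#' @param out_dir run directory for persisted artifacts.
#' @param patches list of patch specs (lists with `center`, and optionally
#'   `radius`, `n_rec`, `p`, `scope`).
#' @return config list.
#' @export
experiment_config <- function(nrows = 100, noise_cells = max(2, nrows %/% 10),
                              master_seed = 1L, out_dir = tempfile("stasrun"),
                              patches = list()) {
  defs <- table1_defaults(nrows)
  list(nrows = defs$nrows, noise_cells = as.integer(noise_cells),
       kernel = defs$kernel, J = defs$J, g = defs$g,
       neuron = defs$neuron,
       noise = noise_params(defs$noise$mu_ext, defs$noise$sigma_ext),
       sim = defs$sim, detection = detection_params(),
       patches = patches, master_seed = as.integer(master_seed),
       out_dir = out_dir)
}

stage_path <- function(config, stage)
  file.path(config$out_dir, paste0(stage, "-", config_hash(config), ".rds"))

load_or_run <- function(config, stage, fun, log) {
  p <- stage_path(config, stage)
  if (file.exists(p)) {
    log("stage ", stage, ": cached")
    return(readRDS(p))
  }
  t0 <- Sys.time()
  x <- fun()
  saveRDS(x, p)
  log("stage ", stage, ": ", round(as.numeric(Sys.time() - t0, units = "secs"), 1), " s")
  x
}

#' Run a full experiment from a config
#'
#' Executes build (geometry, direction field, connectome), simulate
#' (`sim$n_seeds` noise realizations), detect (sequence catalogs), and
#' analyze (sequence landscape, merge tree, per-patch network effects).
#' Artifacts are cached in `config$out_dir` under the config hash; rerunning
#' with an identical config reuses them and reproduces identical results.
#'
#' @param config an [experiment_config()] list.
#' @param verbose print stage timings (default TRUE).
#' @return list with `connectome`, `baseline` (run summaries, sequences,
#'   landscape, tree), `patch_effects` (one row per patch), and `manifest`.
#' @export
run_experiment <- function(config, verbose = TRUE) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- if (verbose) function(...) message(...) else function(...) invisible()

  built <- load_or_run(config, "build", function() {
    geometry <- build_grid(config$nrows)
    field <- sample_direction_field(geometry, config$noise_cells,
                                    derive_seed(config$master_seed, "field"))
    conn <- build_connectome(geometry, field, config$kernel, config$J,
                             config$g, derive_seed(config$master_seed, "connectivity"))
    list(geometry = geometry, field = field, connectome = conn)
  }, log)

  run_once <- function(conn, label, s) {
    noise <- config$noise
    noise$seed <- derive_seed(config$master_seed, paste0("noise-", label), s)
    trace <- simulate_rates(conn, config$neuron, noise, config$sim)
    detect_sequences(trace, config$detection, built$geometry)
  }

  baseline <- load_or_run(config, "baseline", function() {
    runs <- lapply(seq_len(config$sim$n_seeds), function(s)
      run_once(built$connectome, "baseline", s))
    summaries <- do.call(rbind, lapply(seq_along(runs), function(s)
      cbind(seed = s, run_summary(runs[[s]]))))
    land <- sequence_landscape(do.call(c, runs), built$geometry)
    tree <- build_max_tree(land, built$geometry)
    list(sequences = runs, summaries = summaries, landscape = land,
         tree = tree)
  }, log)

  patch_effects <- NULL
  if (length(config$patches)) {
    patch_effects <- load_or_run(config, "patches", function() {
      do.call(rbind, lapply(seq_along(config$patches), function(pi) {
        ps <- config$patches[[pi]]
        patch <- make_patch(ps$center, ps$radius %||% 6, ps$n_rec %||% 40,
                            ps$p %||% 0.10, built$geometry,
                            derive_seed(config$master_seed, "patch", pi),
                            ps$scope %||% "ee")
        conn <- apply_patch(built$connectome, patch)
        runs <- lapply(seq_len(config$sim$n_seeds), function(s)
          run_once(conn, paste0("patch-", pi), s))
        summ <- do.call(rbind, lapply(seq_along(runs), function(s)
          cbind(seed = s, run_summary(runs[[s]]))))
        cbind(patch = pi, network_effect_summary(baseline$summaries, summ))
      }))
    }, log)
  }

  manifest <- list(hash = config_hash(config), master_seed = config$master_seed,
                   nrows = config$nrows, n_seeds = config$sim$n_seeds,
                   timestamp = as.character(Sys.time()))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  list(connectome = built$connectome, baseline = baseline,
       patch_effects = patch_effects, manifest = manifest)
}

#' Deterministic test fixtures
#'
#' Small, fully synthetic inputs with planted structure, used by the test
#' suite and available for exploration:
#' \describe{
#'   \item{grid}{a small toroidal geometry (`params$nrows`, default 16)}
#'   \item{cloud}{an (x, y, t) event cloud with planted Gaussian space-time
#'     clusters (`params$clusters`: list of `center = c(x, y, t)`, `n`,
#'     `spread`, `t_spread`), labels attached as attribute `planted`}
#'   \item{landscape}{a two-plateau count landscape joined by a planted
#'     ridge (`params`: `nrows`, `h` plateau height, `ridge` ridge height);
#'     the ridge cells are attached as attribute `bridge`}
#'   \item{task}{a Y-junction task circuit on a `params$nrows` grid (see
#'     [task_spec()]), with a straight main path splitting into two branches}
#' }
#'
#' @param kind one of `"grid"`, `"cloud"`, `"landscape"`, `"task"`.
#' @param params list of kind-specific parameters (all optional).
#' @param seed RNG seed for stochastic fixtures.
#' @return the fixture object.
#' @export
generate_fixtures <- function(kind = c("grid", "cloud", "landscape", "task"),
                              params = list(), seed = 1L) {
  kind <- match.arg(kind)
  switch(kind,
    grid = build_grid(params$nrows %||% 16),
    cloud = fixture_cloud(params, seed),
    landscape = fixture_landscape(params),
    task = fixture_task(params)
  )
}

fixture_cloud <- function(params, seed) {
  nrows <- params$nrows %||% 40
  clusters <- params$clusters %||% list(
    list(center = c(10, 10, 100), n = 80, spread = 1.5, t_spread = 10),
    list(center = c(30, 12, 400), n = 80, spread = 1.5, t_spread = 10),
    list(center = c(12, 30, 700), n = 80, spread = 1.5, t_spread = 10)
  )
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  parts <- lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    data.frame(
      x = round(cl$center[1] + stats::rnorm(cl$n, 0, cl$spread)) %% nrows,
      y = round(cl$center[2] + stats::rnorm(cl$n, 0, cl$spread)) %% nrows,
      t = round(cl$center[3] + stats::runif(cl$n, -cl$t_spread, cl$t_spread)),
      planted = i
    )
  })
  cloud <- do.call(rbind, parts)
  rownames(cloud) <- NULL
  cloud$neuron <- as.integer(cloud$y * nrows + cloud$x + 1L)
  planted <- cloud$planted
  cloud$planted <- NULL
  attr(cloud, "nrows") <- nrows
  attr(cloud, "planted") <- planted
  class(cloud) <- c("stas_cloud", "data.frame")
  cloud
}

fixture_landscape <- function(params) {
  nrows <- params$nrows %||% 20
  h <- params$h %||% 3
  ridge <- params$ridge %||% 1
  count <- matrix(0L, nrows, nrows)  # [x+1, y+1]
  yb <- 8:12
  count[3:7, yb] <- as.integer(h)
  count[(nrows - 6):(nrows - 2), yb] <- as.integer(h)
  bridge_x <- 8:(nrows - 7)
  count[bridge_x, 10] <- as.integer(ridge)
  bridge <- as.integer((10 - 1) * nrows + (bridge_x - 1) + 1L)
  land <- structure(list(count = as.integer(count), nrows = nrows),
                    class = "stas_landscape")
  attr(land, "bridge") <- bridge
  land
}

# Task circuits are designed on a 40x40 torus: a wide source cone on the
# left nucleates sequences; river-style pathways carry them rightward; an
# unreliable element (a gap bridged by a small funnel cone, or symmetric
# branch mouths behind such gaps) makes transmission probabilistic, so
# +/-10% patches placed on the motif locations modulate it in either
# direction.  The geometry of each topology is a versioned fixture.
fixture_task <- function(params) {
  nrows <- params$nrows %||% 40
  if (nrows < 40) stop("task fixtures need nrows >= 40")
  topology <- params$topology %||% "line"
  mid <- nrows / 2
  w <- params$width %||% 4
  g <- build_grid(nrows)
  src <- function(apex, angle = 0) source_spec(apex, angle, length = 8,
                                               halfwidth = 12)
  funnel <- function(apex, angle = 0, halfwidth = 2)
    source_spec(apex, angle, length = 4, halfwidth = halfwidth)
  bang <- atan2(6, 8)  # branch take-off angle
  switch(topology,
    # one pathway with an unreliable gap: source -> river -> gap+funnel ->
    # river -> fan; Start patch at the source apex, Repeat/Stop at the gap
    line = task_spec(
      pathways = list(
        main1 = pathway_spec(rbind(c(8, mid), c(17, mid)), w, fan = FALSE),
        main2 = pathway_spec(rbind(c(24, mid), c(33, mid)), w)
      ),
      sources = list(S = src(c(8, mid)), m = funnel(c(24, mid))),
      motif_patches = list(
        starter = make_patch(c(7, mid), 6, 40, +0.10, g, seed = 71),
        repeat_up = make_patch(c(20.5, mid), 6, 40, +0.10, g, seed = 72),
        stop_down = make_patch(c(20.5, mid), 6, 40, -0.10, g, seed = 72),
        anti = make_patch(c(27, mid), 6, 40, +0.10, g, seed = 73)
      ),
      spots = list(pre = detection_spot("pre", c(13, mid)),
                   post = detection_spot("post", c(29, mid)))
    ),
    # divergence: main river ends at a gap; two symmetric branch mouths
    # (funnels) compete for the arriving activity; Select patches at the
    # branch mouths bias the choice
    split = task_spec(
      pathways = list(
        main = pathway_spec(rbind(c(8, mid), c(20, mid)), w, fan = FALSE),
        b1 = pathway_spec(rbind(c(23, mid + 2), c(31, mid + 8)), w),
        b2 = pathway_spec(rbind(c(23, mid - 2), c(31, mid - 8)), w)
      ),
      sources = list(S = src(c(8, mid)),
                     m1 = funnel(c(23, mid + 2), bang),
                     m2 = funnel(c(23, mid - 2), -bang)),
      motif_patches = list(
        select_B1_up = make_patch(c(26, mid + 4), 6, 40, +0.10, g, seed = 81),
        select_B1_down = make_patch(c(26, mid + 4), 6, 40, -0.10, g, seed = 81),
        select_B2_up = make_patch(c(26, mid - 4), 6, 40, +0.10, g, seed = 82),
        select_B2_down = make_patch(c(26, mid - 4), 6, 40, -0.10, g, seed = 82)
      ),
      spots = list(S = detection_spot("S", c(12, mid)),
                   M = detection_spot("M", c(16, mid)),
                   B1 = detection_spot("B1", c(28, mid + 6)),
                   B2 = detection_spot("B2", c(28, mid - 6)))
    ),
    # convergence: two sourced branches merge into one main river; a Gate
    # patch on branch b1 just before the merge blocks or boosts it
    merge = task_spec(
      pathways = list(
        b1 = pathway_spec(rbind(c(8, mid + 8), c(20, mid)), w, fan = FALSE),
        b2 = pathway_spec(rbind(c(8, mid - 8), c(20, mid)), w, fan = FALSE),
        main = pathway_spec(rbind(c(20, mid), c(32, mid)), w)
      ),
      sources = list(S1 = source_spec(c(8, mid + 8), atan2(-8, 12),
                                      length = 8, halfwidth = 10),
                     S2 = source_spec(c(8, mid - 8), atan2(8, 12),
                                      length = 8, halfwidth = 10)),
      motif_patches = list(
        gate_down = make_patch(c(14, mid + 4), 6, 40, -0.10, g, seed = 78),
        gate_up = make_patch(c(14, mid + 4), 6, 40, +0.10, g, seed = 78)
      ),
      spots = list(B1 = detection_spot("B1", c(12, mid + 5.3)),
                   B2 = detection_spot("B2", c(12, mid - 5.3)),
                   M = detection_spot("M", c(26, mid)))
    ),
    # context-reversal circuit: as `split`, with the two Select patches used
    # in opposite signs per context to route S -> L (context A) or S -> R
    # (context B)
    context = task_spec(
      pathways = list(
        signal = pathway_spec(rbind(c(8, mid), c(20, mid)), w, fan = FALSE),
        left = pathway_spec(rbind(c(23, mid + 2), c(31, mid + 8)), w),
        right = pathway_spec(rbind(c(23, mid - 2), c(31, mid - 8)), w)
      ),
      sources = list(S = src(c(8, mid)),
                     mL = funnel(c(23, mid + 2), bang),
                     mR = funnel(c(23, mid - 2), -bang)),
      motif_patches = list(
        select_L_up = make_patch(c(26, mid + 4), 6, 40, +0.10, g, seed = 81),
        select_L_down = make_patch(c(26, mid + 4), 6, 40, -0.10, g, seed = 81),
        select_R_up = make_patch(c(26, mid - 4), 6, 40, +0.10, g, seed = 82),
        select_R_down = make_patch(c(26, mid - 4), 6, 40, -0.10, g, seed = 82)
      ),
      spots = list(S = detection_spot("S", c(12, mid)),
                   M1 = detection_spot("M1", c(16, mid)),
                   M2 = detection_spot("M2", c(19, mid)),
                   L = detection_spot("L", c(28, mid + 6)),
                   R = detection_spot("R", c(28, mid - 6))),
      contexts = list(A = c("select_L_up", "select_R_down"),
                      B = c("select_R_up", "select_L_down"))
    ),
    stop("unknown task topology: ", topology)
  )
}
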