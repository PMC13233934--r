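# Anisotropic Mexican-hat connectome construction.
#
# Every neuron makes a fixed number of connections onto the excitatory and
# onto the inhibitory population; target positions are Gaussian around the
# presynaptic neuron (sigma_exc for excitatory senders, sigma_inh for
# inhibitory senders).  Excitatory senders displace their kernel center by
# `shift` grid points along their preferred direction phi, which breaks the
# symmetry of the Mexican hat and lets activity travel.  Multiple synapses
# per pair are allowed (multiplicity k); self-connections are redrawn.

#' Connectivity kernel parameters
#'
#' @param sigma_exc spatial spread of excitatory projections (grid points).
#' @param sigma_inh spread of inhibitory projections; must exceed `sigma_exc`
#'   for the Mexican-hat regime (local excitation, broad inhibition).
#' @param shift displacement of the excitatory kernel center along the
#'   preferred direction phi (grid points).  Default 1: the smallest
#'   displacement that biases a few percent of targets toward phi.
#' @param n_out_exc,n_out_inh connections formed by every neuron onto the
#'   excitatory / inhibitory population.
#' @return a `stas_kernel` list.
#' @export
kernel_params <- function(sigma_exc = 2.5, sigma_inh = 4.5, shift = 1,
                          n_out_exc = 3750, n_out_inh = 938) {
  stopifnot_scalar(sigma_exc, "sigma_exc", positive = TRUE)
  stopifnot_scalar(sigma_inh, "sigma_inh", positive = TRUE)
  if (sigma_inh <= sigma_exc)
    stop("Mexican-hat regime requires sigma_inh > sigma_exc")
  if (shift < 0) stop("`shift` must be >= 0")
  if (n_out_exc <= 0 || n_out_inh <= 0) stop("out-degrees must be > 0")
  structure(list(sigma_exc = sigma_exc, sigma_inh = sigma_inh, shift = shift,
                 n_out_exc = as.integer(n_out_exc),
                 n_out_inh = as.integer(n_out_inh)),
            class = "stas_kernel")
}

#' Reference network parameters, optionally rescaled to a smaller grid
#'
#' Returns the full parameter set of the reference 100x100 network
#' (see the methods vignette for the table).  For a reduced grid the
#' out-degrees are scaled with the area ratio `(nrows/100)^2` and the base
#' weight `J` is scaled inversely, so the mean synaptic input mass per neuron
#' -- and hence the operating point of the dynamics -- is preserved.
#'
#' @param nrows grid side length (default 100, the reference scale).
#' @return list with `nrows`, `kernel`, `J`, `g`, `neuron`, `noise`, `sim`
#'   blocks.
#' @export
table1_defaults <- function(nrows = 100) {
  s <- (nrows / 100)^2
  list(
    nrows = as.integer(nrows),
    kernel = kernel_params(sigma_exc = 2.5, sigma_inh = 4.5, shift = 1,
                           n_out_exc = max(1, round(3750 * s)),
                           n_out_inh = max(1, round(938 * s))),
    J = 0.275 / s,
    g = 8,
    neuron = neuron_params(tau_m = 12, beta = 0.25, i0 = 50),
    noise = list(mu_ext = 0, sigma_ext = 30),
    sim = sim_config(t_sim = 4000, t_warmup = 400, dt = 1)
  )
}

# snap continuous coordinates to the nearest excitatory lattice site (id)
snap_to_exc <- function(x, y, nrows) {
  xi <- round(x) %% nrows
  yi <- round(y) %% nrows
  as.integer(yi * nrows + xi + 1L)
}

# snap to the nearest inhibitory site of the offset lattice (spacing 2,
# anchored at +0.5); returns ids local to the inhibitory population
snap_to_inh <- function(x, y, nrows) {
  half <- nrows %/% 2L
  xi <- round((x - 0.5) / 2) %% half
  yi <- round((y - 0.5) / 2) %% half
  as.integer(yi * half + xi + 1L)
}

#' Build the anisotropic connectome
#'
#' Draws all outgoing connections of every neuron.  Excitatory senders draw
#' target positions from an isotropic Gaussian (`sigma_exc`) centered at their
#' own position displaced by `shift * (cos phi, sin phi)`; inhibitory senders
#' draw isotropically (`sigma_inh`) around themselves.  Draws are snapped to
#' the nearest lattice site of the target population, wrapped toroidally, and
#' tabulated into integer multiplicities `k`.  Self-connection draws are
#' redrawn, so per-neuron out-degrees are conserved exactly.  Weights are
#' `k * J` for excitatory senders and `-k * g * J` for inhibitory senders.
#'
#' @param geometry a [build_grid()] object.
#' @param field a [sample_direction_field()] or [compile_task_field()] object.
#' @param kernel a [kernel_params()] object.
#' @param J base excitatory synaptic weight (> 0).
#' @param g inhibition/excitation weight ratio (> 0).
#' @param seed integer RNG seed for the connectivity draws.
#' @return `stas_connectome`: list with sparse `multiplicity` and `weights`
#'   matrices (post x pre, excitatory ids first), population sizes, and all
#'   construction parameters.
#' @export
build_connectome <- function(geometry, field, kernel, J = 0.275, g = 8, seed = 1L) {
  stopifnot_scalar(J, "J"); stopifnot_scalar(g, "g")
  if (J <= 0 || g <= 0) stop("`J` and `g` must be > 0")
  nrows <- geometry$nrows
  n_exc <- nrow(geometry$exc_positions)
  n_inh <- nrow(geometry$inh_positions)
  n_tot <- n_exc + n_inh
  if (length(field$phi) != n_exc)
    stop("direction field does not match geometry")

  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)

  # the anisotropic displacement applies to E->E projections only: shifting
  # the E->I kernel as well would place feed-forward inhibition ahead of a
  # traveling front and no moving activity could survive
  shift_vec <- kernel$shift * field$has_direction
  exc_centers <- geometry$exc_positions +
    cbind(shift_vec * cos(field$phi), shift_vec * sin(field$phi))

  draw_block <- function(pre_ids, centers, sigma, target, pre_offset) {
    # one column block of the multiplicity matrix: all draws of `pre_ids`
    n_pre <- length(pre_ids)
    n_out <- if (target == "exc") kernel$n_out_exc else kernel$n_out_inh
    total <- n_pre * n_out
    cx <- rep(centers[, 1], each = n_out) + stats::rnorm(total, 0, sigma)
    cy <- rep(centers[, 2], each = n_out) + stats::rnorm(total, 0, sigma)
    tid <- if (target == "exc") snap_to_exc(cx, cy, nrows)
           else snap_to_inh(cx, cy, nrows)
    # redraw self-connections (only possible within the sender's population)
    same_pop <- (target == "exc" && pre_offset == 0L) ||
                (target == "inh" && pre_offset == n_exc)
    if (same_pop) {
      loc <- rep(seq_along(pre_ids), each = n_out)  # chunk-local row index
      bad <- which(tid == rep(pre_ids, each = n_out))
      while (length(bad)) {
        cxb <- centers[loc[bad], 1] + stats::rnorm(length(bad), 0, sigma)
        cyb <- centers[loc[bad], 2] + stats::rnorm(length(bad), 0, sigma)
        tid[bad] <- if (target == "exc") snap_to_exc(cxb, cyb, nrows)
                    else snap_to_inh(cxb, cyb, nrows)
        bad <- bad[tid[bad] == pre_ids[loc[bad]]]
      }
    }
    post_global <- tid + if (target == "exc") 0L else n_exc
    Matrix::sparseMatrix(
      i = post_global, j = rep(seq_len(n_pre), each = n_out), x = 1,
      dims = c(n_tot, n_pre)
    )
  }

  build_columns <- function(pre_ids, centers_exc_target, centers_inh_target,
                            sigma, pre_offset) {
    chunk <- max(1L, floor(4e6 / (kernel$n_out_exc + kernel$n_out_inh)))
    starts <- seq(1L, length(pre_ids), by = chunk)
    blocks <- lapply(starts, function(s) {
      idx <- s:min(s + chunk - 1L, length(pre_ids))
      draw_block(pre_ids[idx], centers_exc_target[idx, , drop = FALSE],
                 sigma, "exc", pre_offset) +
        draw_block(pre_ids[idx], centers_inh_target[idx, , drop = FALSE],
                   sigma, "inh", pre_offset)
    })
    do.call(cbind, blocks)
  }

  K_from_exc <- build_columns(seq_len(n_exc), exc_centers,
                              geometry$exc_positions, kernel$sigma_exc, 0L)
  K_from_inh <- build_columns(seq_len(n_inh), geometry$inh_positions,
                              geometry$inh_positions, kernel$sigma_inh, n_exc)
  K <- cbind(K_from_exc, K_from_inh)
  col_scale <- c(rep(J, n_exc), rep(-g * J, n_inh))
  W <- K %*% Matrix::Diagonal(x = col_scale)

  structure(
    list(multiplicity = methods::as(K, "CsparseMatrix"),
         weights = methods::as(W, "CsparseMatrix"),
         J = J, g = g, n_exc = n_exc, n_inh = n_inh,
         geometry = geometry, field = field, kernel = kernel, seed = seed),
    class = "stas_connectome"
  )
}

#' @method print stas_connectome
#' @export
print.stas_connectome <- function(x, ...) {
  cat("stas_connectome: ", x$n_exc, " E + ", x$n_inh, " I neurons on a ",
      x$geometry$nrows, "x", x$geometry$nrows, " torus\n",
      "  out-degrees ", x$kernel$n_out_exc, " (exc targets) / ",
      x$kernel$n_out_inh, " (inh targets); J = ", signif(x$J, 4),
      ", g = ", x$g, "\n", sep = "")
  invisible(x)
}

#' Summed outgoing multiplicities per neuron
#'
#' Tallies, for every presynaptic neuron, the total number of formed
#' connections onto the excitatory and onto the inhibitory population.  By
#' construction both tallies are constant across neurons (out-degree
#' conservation).
#'
#' @param connectome a [build_connectome()] object.
#' @return list with integer vectors `onto_exc` and `onto_inh` (one entry per
#'   presynaptic neuron).
#' @export
out_degrees <- function(connectome) {
  K <- connectome$multiplicity
  ne <- connectome$n_exc
  list(
    onto_exc = Matrix::colSums(K[seq_len(ne), , drop = FALSE]),
    onto_inh = Matrix::colSums(K[(ne + 1):nrow(K), , drop = FALSE])
  )
}

#' Weighted excitatory in-degree landscape
#'
#' Per-excitatory-neuron sum of incoming excitatory-to-excitatory weights
#' (`k * J` mass).  Inhibitory inputs are excluded: they are isotropic and
#' symmetric and only act as an offset.  The spatial map of this quantity is
#' the in-degree landscape whose mid/high regions carry the pathways.
#'
#' @param connectome a [build_connectome()] object.
#' @return numeric vector, one value per excitatory neuron.
#' @export
in_degree_landscape <- function(connectome) {
  ne <- connectome$n_exc
  Matrix::rowSums(connectome$weights[seq_len(ne), seq_len(ne), drop = FALSE])
}

#' Classify the in-degree landscape into five domains
#'
#' Splits the in-degree range into five equal-width bins: low, low-mid, mid,
#' mid-high, high.  With `clip` given (percent pair, e.g. `c(2.5, 97.5)`), the
#' binning range is the inner percentile interval and values outside it fall
#' into the extreme bins; this keeps rare outliers from emptying the low/high
#' domains when classifying patches.
#'
#' @param in_degree numeric vector of per-neuron in-degrees.
#' @param clip `NULL` (full range) or a length-2 percentile pair.
#' @return `stas_domains`: list with `in_degree`, `domain_label` (factor),
#'   `bin_edges` (6 thresholds), `clip_percentiles`.
#' @export
classify_domains <- function(in_degree, clip = NULL) {
  if (!length(in_degree)) stop("`in_degree` must be nonempty")
  lev <- c("low", "low-mid", "mid", "mid-high", "high")
  if (is.null(clip)) {
    lo <- min(in_degree); hi <- max(in_degree)
  } else {
    if (length(clip) != 2L) stop("`clip` must be a percentile pair")
    q <- stats::quantile(in_degree, clip / 100, names = FALSE)
    lo <- q[1]; hi <- q[2]
  }
  if (hi <= lo) {
    warning("constant in-degree field: degenerate single-bin labeling")
    lab <- factor(rep("low", length(in_degree)), levels = lev)
    return(structure(list(in_degree = in_degree, domain_label = lab,
                          bin_edges = rep(lo, 6), clip_percentiles = clip),
                     class = "stas_domains"))
  }
  edges <- seq(lo, hi, length.out = 6)
  idx <- findInterval(in_degree, edges, all.inside = TRUE)
  idx[in_degree < lo] <- 1L
  idx[in_degree > hi] <- 5L
  structure(list(in_degree = in_degree,
                 domain_label = factor(lev[idx], levels = lev),
                 bin_edges = edges, clip_percentiles = clip),
            class = "stas_domains")
}

#' Export a connectome as a plain-text edge list
#'
#' Writes one row per connected (pre, post) pair with multiplicity `k` and
#' weight `w`, tab-separated, for interoperability with graph tools.
#'
#' @param connectome a [build_connectome()] object.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
export_edges <- function(connectome, path) {
  K <- methods::as(connectome$multiplicity, "TsparseMatrix")
  W <- methods::as(connectome$weights, "TsparseMatrix")
  df <- data.frame(pre = K@j + 1L, post = K@i + 1L, k = K@x, w = W@x)
  df <- df[order(df$pre, df$post), ]
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
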