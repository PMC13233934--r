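# Local synaptic modulation ("patches").
#
# A patch mimics the spatially localized release of a neuromodulator: from a
# disk of radius r (default 6 grid points) a fixed number of excitatory
# neurons (default 40) is sampled, and the incoming synaptic weights of those
# neurons are scaled by (1 + p), p = +/-10% by default.  The modulation is
# tonic: applied to the weight matrix once, before simulation.

#' Define a modulation patch
#'
#' Samples `n_rec` excitatory neurons uniformly without replacement from the
#' closed disk of `radius` around `center`.
#'
#' @param center 2D patch center (grid coordinates).
#' @param radius disk radius in grid points (default 6).
#' @param n_rec number of modulated neurons (default 40).
#' @param p signed relative weight change (default +0.10); must be > -1.
#' @param geometry a [build_grid()] object.
#' @param seed RNG seed for the neuron selection (independent of noise and
#'   connectivity seeds).
#' @param scope which incoming synapses are scaled: `"ee"` (default,
#'   excitatory-to-excitatory only) or `"all"` (all incoming).
#' @return `stas_patch`: list with the arguments plus `selected` neuron ids
#'   and `disk_size`.
#' @export
make_patch <- function(center, radius = 6, n_rec = 40, p = 0.10, geometry,
                       seed = 1L, scope = c("ee", "all")) {
  scope <- match.arg(scope)
  if (p <= -1) stop("`p` must be > -1 (weights cannot flip sign)")
  disk <- neurons_in_disk(center, radius, geometry, "exc")
  if (length(disk) < n_rec)
    stop("patch disk holds only ", length(disk), " excitatory neurons, ",
         "cannot select n_rec = ", n_rec)
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  selected <- sort(sample(disk, n_rec))
  structure(list(center = center, radius = radius, n_rec = as.integer(n_rec),
                 p = p, selected = selected, disk_size = length(disk),
                 seed = seed, scope = scope),
            class = "stas_patch")
}

# scale the scoped incoming weights of `selected` (excitatory) neurons
scale_incoming <- function(connectome, selected, p, scope) {
  if (!scope %in% c("ee", "all")) stop("unknown scope: ", scope)
  W <- connectome$weights
  K <- connectome$multiplicity
  n_exc <- connectome$n_exc
  if (any(selected < 1 | selected > n_exc))
    stop("selected neurons must be excitatory ids")
  fac <- 1 + p
  if (scope == "ee") {
    W[selected, seq_len(n_exc)] <- W[selected, seq_len(n_exc)] * fac
  } else {
    W[selected, ] <- W[selected, ] * fac
  }
  out <- connectome
  out$weights <- W
  out$multiplicity <- K
  out
}

#' Apply a patch to a connectome
#'
#' Returns a modulated copy: the scoped incoming weights of the patch's
#' selected neurons are multiplied by `(1 + p)`; everything else is
#' unchanged, and the input connectome is not modified.  The modulation is
#' static and persists for the whole simulation.
#'
#' @param connectome a [build_connectome()] object.
#' @param patch a [make_patch()] object.
#' @return modulated `stas_connectome` (with a `patch` attribute).
#' @export
apply_patch <- function(connectome, patch) {
  out <- scale_incoming(connectome, patch$selected, patch$p, patch$scope)
  attr(out, "patch") <- patch
  out
}

#' Non-spatial modulation control
#'
#' Same scaling rule as [apply_patch()], but the `n_rec` neurons are sampled
#' uniformly from the whole excitatory population instead of a local disk.
#' Comparing patch versus non-spatial modulation isolates the cooperative
#' effect of shared local connectivity.
#'
#' @param connectome a [build_connectome()] object.
#' @param n_rec number of modulated neurons.
#' @param p signed relative weight change.
#' @param seed RNG seed for the selection.
#' @param scope `"ee"` or `"all"`, as in [make_patch()].
#' @return modulated `stas_connectome` (with a `control_selected` attribute).
#' @export
apply_nonspatial_control <- function(connectome, n_rec = 40, p = 0.10,
                                     seed = 1L, scope = c("ee", "all")) {
  scope <- match.arg(scope)
  if (p <= -1) stop("`p` must be > -1")
  if (n_rec > connectome$n_exc)
    stop("`n_rec` exceeds the excitatory population size")
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  selected <- sort(sample(connectome$n_exc, n_rec))
  out <- scale_incoming(connectome, selected, p, scope)
  attr(out, "control_selected") <- selected
  out
}
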