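---
title: "Controlling spatio-temporal activity sequences: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Controlling spatio-temporal activity sequences: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`stasnet` simulates and analyzes spatio-temporal activity sequences (STAS) in
a recurrent firing-rate network on a toroidal grid. Each of the
$n_\mathrm{rows}^2$ excitatory and $n_\mathrm{rows}^2/4$ inhibitory units
follows

$$\tau_M \frac{dr}{dt} = -r + \Phi(I(t)), \qquad
\Phi(I) = \frac{1}{1 + e^{\beta (I_0 - I)}},$$

with total input $I_\mathrm{post}(t) = \sum_\mathrm{pre}
w_\mathrm{post,pre}\, r_\mathrm{pre}(t) - I_\mathrm{ext}(t)$. The external
drive is a discrete-time approximation of Gaussian white noise: one
independent draw $\mathcal N(\mu_\mathrm{ext}, \sigma_\mathrm{ext}^2)$ per
neuron per time step. Rates live in $(0, 1)$; with forward Euler at
$\delta t \le \tau_M$ each step is a convex combination of $r$ and
$\Phi(I)$, so the unit interval is invariant.

Connectivity is a Mexican hat made anisotropic. Every neuron forms a fixed
number of connections onto the excitatory and onto the inhibitory population
(multiple synapses per pair allowed, self-connections redrawn); target
positions are Gaussian around the sender with spread $\sigma_\mathrm{exc}$
for excitatory senders and the larger $\sigma_\mathrm{inh}$ for inhibitory
senders — local excitation, broad inhibition. Excitatory-to-excitatory draws
are additionally displaced by `shift` grid points along the sender's
preferred direction $\phi$; when the $\phi$ of neighboring neurons are
similar (sampled from spatially correlated gradient noise), this asymmetry
destabilizes stationary bumps into traveling ones, and the convergence of
shifted kernels produces a smooth landscape of excitatory in-degree whose
mid and high ridges are the pathways along which sequences run.

Reference parameters (the defaults of `table1_defaults()`):

| parameter | value | meaning |
|---|---|---|
| `nrows` | 100 | grid side (10,000 E + 2,500 I neurons) |
| `I0`, `beta` | 50, 0.25 | half-activation input, transfer steepness |
| `tau_m` | 12 ms | membrane time constant |
| `J`, `g` | 0.275, 8 | base weight; inhibition/excitation ratio |
| `mu_ext`, `sigma_ext` | 0, 30 | external-drive mean and SD |
| `t_sim`, `t_warmup`, `dt` | 4000, 400, 1 ms | simulated, discarded, step |
| `sigma_exc`, `sigma_inh` | 2.5, 4.5 | kernel spreads (grid points) |
| out-degrees | 3,750 / 938 | connections onto E / I per neuron |
| `shift` | 1 | kernel displacement along $\phi$ (grid points) |

# Design choices in the connectivity

**Which projections are shifted.** Only excitatory-to-excitatory draws use
the anisotropic displacement; excitatory-to-inhibitory and all inhibitory
projections are isotropic. This is a substantive dynamical requirement, not
a convenience: if the E$\to$I kernel is also shifted, the feed-forward
inhibition recruited by a moving activity bump lands *ahead* of it, and in
our integrator no traveling solution survives at the reference parameters.
With the E$\to$E-only shift, spontaneous propagating sequences emerge at
`shift = 1`; at `shift >= 2` the network saturates into persistent global
activity. We verified both regimes with seeded-bump experiments before
fixing the default.

**Gradient noise.** Preferred directions come from classic 2D lattice
gradient (Perlin) noise: random unit gradients on a
`noise_cells` $\times$ `noise_cells` lattice, quintic interpolation, and the
lattice index wrapped modulo `noise_cells`, which makes the field *exactly*
periodic across the torus seam (no 4D embedding or mirror blending needed).
Neurons are sampled at cell-interior points (offset one half grid spacing)
because the noise vanishes identically on the gradient lattice itself. The
scalar field is mapped linearly from its observed range onto $[0, 2\pi)$,
preserving smoothness. `noise_cells` sets the correlation length and hence
the pathway width; we use 10 cells at `nrows = 100` (and 4 at 40) so that
several distinct pathways coexist, and note that published landscapes are
not bit-reproducible — only statistically equivalent.

**Snapping and out-degree conservation.** Continuous Gaussian draws are
snapped to the nearest lattice site of the target population (integer
lattice for E, offset spacing-2 lattice for I) and wrapped toroidally;
self-connection draws are redrawn rather than dropped, so every neuron's
out-degrees are conserved exactly — 3,750 onto E and 938 onto I at reference
settings, which the acceptance suite checks on a full-size build.

**Reduced grids.** `table1_defaults(nrows)` scales the out-degrees with the
area ratio $(n_\mathrm{rows}/100)^2$ *and* the base weight $J$ inversely, so
the mean weighted E$\to$E in-degree mass (1,031 J-units) — and with it the
operating point of the dynamics — is preserved. Without the $J$
compensation a reduced grid is silent. The relative sampling noise of the
in-degree landscape grows as out-degrees shrink; the designed task circuits
below therefore keep the full 3,750/938 out-degrees even on the 40-grid.

# Sequence detection

Rates of excitatory neurons are thresholded at $\Theta = 0.4$ (inclusive)
into pseudo-spike events $(x, y, t)$, then clustered with DBSCAN
($\epsilon = 4$, `min_samples` $= 50$) in the mixed space $(x, y,
\mathrm{time\_scale}\cdot t)$ with `time_scale = 1` (time in raw ms; the
rescaling has little effect and is exposed). Because the grid is a torus,
clustering runs a second time with both spatial axes shifted by
`nrows`/2, and clusters from the two passes sharing at least one event are
merged transitively; events noise in both passes are discarded. The single
simultaneous diagonal shift has one blind spot worth knowing: a cluster
centered near `(0, nrows/2)` or `(nrows/2, 0)` straddles the x-seam in the
first pass *and* the y-seam in the second, so neither pass sees it whole;
clusters anywhere else — including corner-straddling ones — are recovered
exactly as under the full toroidal metric. Sequences
whose spatial extent — the maximum pairwise *toroidal* distance between
their event coordinates, the most conservative reading of "traverse" —
falls below 8 grid points are removed; a run whose raw clusters contain a
stationary saturated cluster (extent below 8 for at least 90% of the
simulated time) is flagged by `is_static_bump_run()` and excluded from
motif analyses. The clustering core is implemented in C++ with a uniform
grid hash; the test suite checks it against a brute-force $O(n^2)$
density clustering under the full toroidal metric, including
seam-straddling planted clusters.

Per-neuron participation counts over the filtered sequences form the
*sequence landscape*; crossings of radius-2 detection spots are defined by
*neuron membership* (a sequence crosses a spot if any participating neuron
lies in the disk), with the first crossing time the earliest event time of
those neurons.

# Merge trees and semi-transmissive bridges

A max-tree over the (integer) sequence-count landscape is built by a
descending threshold sweep with toroidal 8-neighborhood connectivity
(8-connectivity avoids spurious diagonal splits of narrow pathways).
Components are born at regional maxima; a merge is recorded at the highest
threshold where two components that both existed strictly above it become
connected, so components born at the merge level itself never count — this
is our admissibility rule for the qualitative "artifact" filtering the
method requires. For each merge, the bridge is formed by cells entering at
the merge threshold within $d_{max} = 4$ of both parent components, plus
their 8-neighbors within 10 grid points of both. On scaled-down (40-grid)
baselines the landscape reliably contains at least one merge; the $\approx
9$ merges per network reported at full scale is a full-scale replication
target, not asserted at desk scale.

# Motifs as designed circuits

At full scale, motif locations are found by inspecting a particular
100-grid network instantiation. For testable, constructible motifs we use
`compile_task_field()` instead: a direction field drawn from a circuit of

* *pathways* — polyline corridors whose neurons point along the tangent,
  bent toward the centerline (`attract`, default 1.2 at the corridor edge)
  so traveling bumps are guided; diverging "fans" at open ends let
  sequences die out instead of piling up at a terminus (a directed corridor
  otherwise accumulates shifted kernel mass at its last column and ignites
  there);
* *source cones* — regions whose neurons all point at an apex; the
  convergent in-degree hotspot nucleates sequences stochastically under the
  noise drive;
* *gaps bridged by small funnel cones* — an interruption of the corridor
  whose crossing probability is tunable by the gap length, giving a
  genuinely unreliable segment.

Off-circuit neurons have *no* preferred direction, i.e. a zero kernel
shift — not a random one. `generate_fixtures("task", ...)` versions four
topologies on the 40-grid: `line` (source, river, 7-point gap, river; the
Start patch sits on the source apex, Repeat/Stop on the gap), `split` (a
main river ending at a gap with two symmetric branch mouths; Select patches
at the mouths), `merge` (two sourced branches converging; Gate patch on one
branch), and `context` (the split circuit with both Select patches driven
in opposite signs per context). Where a junction's behavior depends on the
random connectivity instantiation, the fixture's connectivity seed is part
of the versioned fixture: we use instances whose junction is balanced
(both branch mouths marginally transmissive) — motifs are always
properties of a particular network instance. Patch effects observed on these
fixtures at $\pm 10\%$, 40 neurons, pooled over 4 noise seeds: Start raises
the sequence count at the upstream spot several-fold; Repeat raises
P(post|pre) (0.24 $\to$ 0.76 on the line instance); Stop abolishes it;
Select raises the modulated branch (0.14 $\to$ 0.73) while the other branch
barely moves, and suppresses it to 0 with the negative sign; Gate weakening
cuts P(M|B1) (0.88 $\to$ 0) without reducing P(M|B2). The context task
reverses P(L|S) versus P(R|S) when the Select patch pair is swapped. These
are direction-of-effect properties: the percentage values themselves
belong to one specific network instantiation and are not reproduction
targets.

The Anti-Repeat motif (a positive patch on the high-in-degree region just
after an unreliable segment suppressing through-traffic) is computed by
`motif_report()` but not sign-asserted: on the designed line fixture the
post-gap patch aids re-ignition instead of spawning competing sequences, so
its sign is fixture-dependent.

# Conditional transmission probabilities

For spots *pre* and *post*, pooled over noise seeds:
$P(\mathrm{post}|\mathrm{pre}) = n_\mathrm{ordered} / n_\mathrm{pre}$ where
$n_\mathrm{ordered}$ counts sequences whose first crossing at *pre* is no
later than at *post* — temporal ordering implements "subsequent
activation". Ratios with zero denominators are `NA`, never 0. Counts are
pooled before dividing (robust to small per-seed denominators);
`transmission_by_run()` provides the per-seed-averaged estimator as a
cross-check. Branch episodes group sequences whose first crossings at the
branch spots fall within `t_window` = 200 ms of the earliest (episodes are
disjoint; the earliest crossing anchors one); cooperation requires one
merged sequence crossing B1, B2 and M, with the merge time defined as the
first millisecond at which the two branch-side event clouds come within
$\epsilon$ of each other; the "maximum competition" time is reported
descriptively as the minimum of summed branch activity between the two
branch crossings; it is descriptive output, not an asserted quantity.

# Numerical and reproducibility choices

* Forward Euler at $\delta t = 1$ ms ($\tau_M = 12$ ms keeps it stable);
  rate state initialized at 0; the first 400 ms are discarded.
* Noise: per-step draws at the stated $\sigma_\mathrm{ext}$; a
  $\sigma/\sqrt{\delta t}$ white-noise-density variant is available as
  `noise_params(scale_sqrt_dt = TRUE)`.
* The minus sign on $I_\mathrm{ext}$ in the input sum is implemented as
  stated; with $\mu_\mathrm{ext} = 0$ it is distribution-neutral.
* Every randomness source (direction field, connectivity, patch selection,
  per-run noise) draws its seed from a named stream via
  `derive_seed(master_seed, label, index)`; identical configs reproduce
  bit-identical connectomes, traces and catalogs, and `run_experiment()`
  caches completed stages under a config hash.
* Degenerate inputs: a constant in-degree field yields a single-bin domain
  labeling with a warning; an all-zero landscape yields an empty merge
  tree; empty pseudo-spike clouds and empty spot-crossing tables flow
  through the pipeline as empty results, not errors.

# What the synthetic fixtures do and do not show

The generators emulate small toroidal grids, planted space-time event
clouds (including seam-straddling clusters), two-plateau count landscapes
with a known ridge, and the designed task circuits. They establish
correctness of the machinery (oracle equivalence, invariances, sign
effects under controlled geometry) — not quantitative properties of
full-scale random networks. Specifically: desk-scale problem sizes are a
40-grid, 4,000 ms simulated per run and 3–6 noise realizations per
condition; the patch-versus-nonspatial *dispersion* comparison and the
$\approx 9$-merges-per-network figure need the full 100-grid, 8-seed,
20-network design and are documented here as full-scale replication
targets rather than asserted at desk scale. Known limitations: rate units
(no spiking variability), tonic modulation only (no neuromodulator
kinetics), no synaptic plasticity, and square toroidal grids only.
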