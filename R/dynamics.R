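# Firing-rate dynamics.
#
#   tau_m * dr/dt = -r + Phi(I),    Phi(I) = 1 / (1 + exp(beta * (i0 - I)))
#   I_post(t) = sum_pre w_post,pre * r_pre(t) - I_ext(t)
#
# integrated with forward Euler at dt; the external drive is an approximation
# of Gaussian white noise, sampled independently per neuron and per step.

#' Rate-neuron parameters
#'
#' @param tau_m membrane time constant (ms).
#' @param beta steepness of the sigmoidal transfer function (1/input units).
#' @param i0 half-activation input: `transfer_function(i0) == 0.5` in the
#'   absence of network input.
#' @return a `stas_neuron` list.
#' @export
neuron_params <- function(tau_m = 12, beta = 0.25, i0 = 50) {
  stopifnot_scalar(tau_m, "tau_m", positive = TRUE)
  stopifnot_scalar(beta, "beta", positive = TRUE)
  stopifnot_scalar(i0, "i0")
  structure(list(tau_m = tau_m, beta = beta, i0 = i0), class = "stas_neuron")
}

#' External-noise parameters
#'
#' Gaussian white-noise approximation: one independent draw
#' `N(mu_ext, sigma_ext)` per neuron per time step.
#'
#' @param mu_ext mean external input.
#' @param sigma_ext external input standard deviation (>= 0).
#' @param seed integer RNG seed for the noise stream.
#' @param scale_sqrt_dt logical; if `TRUE` the per-step standard deviation is
#'   `sigma_ext / sqrt(dt)` (white-noise density convention).  Default
#'   `FALSE`: per-step draws at the stated sigma, matching the discrete
#'   per-neuron-per-step sampling contract at dt = 1 ms.
#' @return a `stas_noise` list.
#' @export
noise_params <- function(mu_ext = 0, sigma_ext = 30, seed = 1L,
                         scale_sqrt_dt = FALSE) {
  stopifnot_scalar(mu_ext, "mu_ext")
  stopifnot_scalar(sigma_ext, "sigma_ext")
  if (sigma_ext < 0) stop("`sigma_ext` must be >= 0")
  structure(list(mu_ext = mu_ext, sigma_ext = sigma_ext, seed = seed,
                 scale_sqrt_dt = isTRUE(scale_sqrt_dt)),
            class = "stas_noise")
}

#' Simulation configuration
#'
#' @param t_sim simulated (recorded) duration in ms.
#' @param t_warmup discarded warm-up duration in ms.
#' @param dt integration time step in ms; `t_sim` and `t_warmup` must be
#'   multiples of `dt`.
#' @param n_seeds number of noise realizations for multi-run experiments.
#' @return a `stas_simconfig` list.
#' @export
sim_config <- function(t_sim = 4000, t_warmup = 400, dt = 1, n_seeds = 8L) {
  stopifnot_scalar(dt, "dt", positive = TRUE)
  if (abs(t_sim / dt - round(t_sim / dt)) > 1e-9 ||
      abs(t_warmup / dt - round(t_warmup / dt)) > 1e-9)
    stop("`t_sim` and `t_warmup` must be multiples of `dt`")
  if (n_seeds < 1) stop("`n_seeds` must be >= 1")
  structure(list(t_sim = t_sim, t_warmup = t_warmup, dt = dt,
                 n_seeds = as.integer(n_seeds)),
            class = "stas_simconfig")
}

#' Sigmoidal rate transfer function
#'
#' `Phi(i) = 1 / (1 + exp(beta * (i0 - i)))`: strictly increasing, bounded in
#' (0, 1), equal to 0.5 exactly at the half-activation input `i0`.
#'
#' @param i input value(s).
#' @param params a [neuron_params()] object.
#' @return rate value(s) in (0, 1).
#' @examples
#' transfer_function(50, neuron_params(beta = 0.25, i0 = 50))  # 0.5
#' @export
transfer_function <- function(i, params = neuron_params()) {
  1 / (1 + exp(params$beta * (params$i0 - i)))
}

#' Total synaptic input per neuron
#'
#' `I_post = sum_pre w_post,pre * r_pre - I_ext`, the recurrent drive minus
#' the external term, as a single sparse matrix-vector product.
#'
#' @param rates per-neuron rate vector (length = total neurons).
#' @param connectome a [build_connectome()] object.
#' @param ext per-neuron external draw (scalar or vector).
#' @return per-neuron input vector.
#' @export
total_input <- function(rates, connectome, ext = 0) {
  n <- connectome$n_exc + connectome$n_inh
  if (length(rates) != n)
    stop("`rates` has length ", length(rates), ", expected ", n)
  as.numeric(connectome$weights %*% rates) - ext
}

#' Integrate the rate dynamics
#'
#' Forward-Euler integration `r <- r + (dt/tau_m) * (-r + Phi(I))` from a
#' zero initial state.  The first `t_warmup` ms are simulated and discarded;
#' the recorded trace covers `t_sim` ms at resolution `dt`.  For
#' `dt <= tau_m` every Euler step is a convex combination of `r` and
#' `Phi(I)`, so rates stay in [0, 1] at every step.
#'
#' @param connectome a [build_connectome()] object.
#' @param neuron a [neuron_params()] object.
#' @param noise a [noise_params()] object (its `seed` fixes the realization).
#' @param config a [sim_config()] object.
#' @param record `"exc"` (default) to record excitatory rates only, or
#'   `"all"`.
#' @return `stas_trace`: list with `rates` (neurons x time-steps matrix),
#'   `time` (ms, warm-up excluded), `record`, `config`, and provenance
#'   (`noise`, `connectome_seed`).
#' @export
simulate_rates <- function(connectome, neuron = neuron_params(),
                           noise = noise_params(), config = sim_config(),
                           record = c("exc", "all")) {
  record <- match.arg(record)
  n <- connectome$n_exc + connectome$n_inh
  W <- connectome$weights
  dt <- config$dt
  n_warm <- as.integer(round(config$t_warmup / dt))
  n_rec <- as.integer(round(config$t_sim / dt))
  alpha <- dt / neuron$tau_m
  sd_step <- if (noise$scale_sqrt_dt) noise$sigma_ext / sqrt(dt) else noise$sigma_ext

  rng <- local_rng(noise$seed)
  on.exit(rng(), add = TRUE)

  n_keep <- if (record == "exc") connectome$n_exc else n
  out <- matrix(0, n_keep, n_rec)
  r <- numeric(n)
  for (step in seq_len(n_warm + n_rec)) {
    ext <- stats::rnorm(n, noise$mu_ext, sd_step)
    input <- as.numeric(W %*% r) - ext
    r <- r + alpha * (transfer_function(input, neuron) - r)
    if (anyNA(r) || any(!is.finite(r)))
      stop("simulation failure: non-finite rates at step ", step)
    if (step > n_warm) out[, step - n_warm] <- r[seq_len(n_keep)]
  }
  structure(
    list(rates = out, time = seq_len(n_rec) * dt, record = record,
         config = config, noise = noise, connectome_seed = connectome$seed,
         nrows = connectome$geometry$nrows),
    class = "stas_trace"
  )
}

#' @method print stas_trace
#' @export
print.stas_trace <- function(x, ...) {
  cat("stas_trace: ", nrow(x$rates), " neurons x ", ncol(x$rates),
      " steps (dt = ", x$config$dt, " ms, warm-up discarded)\n", sep = "")
  invisible(x)
}

#' Mean recurrent input across neurons and time
#'
#' Time- and population-average of the recurrent term `sum_pre w * r_pre`
#' over a recorded trace.  In the reference inhibition-stabilized regime this
#' mean is negative.
#'
#' @param trace a [simulate_rates()] trace recorded with `record = "all"`.
#' @param connectome the matching connectome.
#' @param n_samples number of evenly spaced time points to average over.
#' @return scalar mean recurrent input.
#' @export
mean_recurrent_input <- function(trace, connectome, n_samples = 200) {
  if (trace$record != "all")
    stop("mean_recurrent_input needs a trace recorded with record = \"all\"")
  steps <- unique(round(seq(1, ncol(trace$rates), length.out = n_samples)))
  rec <- connectome$weights %*% trace$rates[, steps, drop = FALSE]
  mean(as.matrix(rec))
}
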