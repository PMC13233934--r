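# Shared, lazily built simulation fixtures.  Builds are deterministic, so
# caching them across test files only saves time.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

grid40 <- function() cached("grid40", function() build_grid(40))

# scaled-down noise-field network in the reference dynamical regime
noise_net40 <- function() cached("noise_net40", function() {
  defs <- table1_defaults(40)
  g <- grid40()
  field <- sample_direction_field(g, 4, seed = 11)
  conn <- build_connectome(g, field, defs$kernel, defs$J, defs$g, seed = 21)
  list(defs = defs, geometry = g, field = field, connectome = conn)
})

# designed task-circuit networks (full reference out-degrees, J = 0.275)
task_net <- function(topology, conn_seed) {
  cached(paste0("task_", topology, "_", conn_seed), function() {
    g <- grid40()
    task <- generate_fixtures("task", list(topology = topology))
    field <- compile_task_field(task, g)
    conn <- build_connectome(g, field, kernel_params(), J = 0.275, g = 8,
                             seed = conn_seed)
    list(task = task, geometry = g, field = field, connectome = conn)
  })
}

# pooled crossings of `n_seeds` noise realizations of a (possibly patched)
# task network
pooled_task_crossings <- function(net, connectome = net$connectome,
                                  n_seeds = 4, t_sim = 4000) {
  g <- net$geometry
  spots <- unname(net$task$spots)
  crs <- lapply(seq_len(n_seeds), function(s) {
    tr <- simulate_rates(connectome, neuron_params(),
                         noise_params(seed = 600 + s),
                         sim_config(t_sim = t_sim, t_warmup = 400))
    spot_crossings(detect_sequences(tr, detection_params(), g), spots, g)
  })
  pool_crossings(crs)
}
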