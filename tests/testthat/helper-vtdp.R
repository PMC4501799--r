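# Shared fixtures. Expensive network states are built once per test run and
# cached; every builder seeds its own RNG so the cache content is
# reproducible regardless of test ordering.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# full 500x10 network, equilibrated under pure spontaneous release
eq_net <- function() memo("eq_net", function() {
  set.seed(vtdp_streams(2024L)[["weights"]])
  equilibrate(network_init(vtdp_config()))
})

# equilibrated network with every presynaptic neuron at the mean rate
# (uncorrelated activity, used by the distribution-shape checks)
eq_net_uniform <- function() memo("eq_net_uniform", function() {
  cfg <- vtdp_config(rate_low = 4.8, rate_high = 4.8)
  set.seed(vtdp_streams(2025L)[["weights"]])
  equilibrate(network_init(cfg))
})

# small network for fast determinism/structure checks
small_config <- function() vtdp_config(n_pre = 50L, n_post = 2L)

pure <- function(mode = c("sve", "aeve", "seve")) {
  mode <- match.arg(mode)
  switch(mode,
         sve = release_fractions(0, 0),
         aeve = release_fractions(1, 0),
         seve = release_fractions(0, 1))
}

const_schedule <- function(mode) switch_schedule(0, pure(mode))

# 3-sigma band for total release counts of an evoked mode over a window in
# which the realized presynaptic spike count fluctuates: the count is
# over-dispersed because all synapses of a neuron (and all n_post targets)
# share its spikes. var_spikes is the variance of the population spike count.
evoked_release_band <- function(expected, var_spikes, n_ves, n_post) {
  3 * sqrt(expected + (n_ves * n_post)^2 * var_spikes)
}

# long pure-spontaneous run of the full network (homeostatic maintenance,
# divergence flatness); snapshots every second
sve_run_300s <- function() memo("sve_run_300s", function() {
  net <- eq_net()
  set.seed(vtdp_streams(2024L)[["spikes"]])
  simulate_vtdp(net, const_schedule("sve"), 300e3)
})

# post-switch runs of the three pure modes from the same equilibrated state
mode_run_200s <- function(mode) memo(paste0("mode200_", mode), function() {
  net <- eq_net()
  k <- match(mode, c("sve", "aeve", "seve"))
  set.seed(vtdp_streams(2024L + k)[["release"]])
  simulate_vtdp(net, const_schedule(mode), 200e3)
})

# variance of the realized spike count for the standard rate pattern
pattern_spike_var <- function(cfg, duration_ms) {
  n_steps <- duration_ms / cfg$dt
  n_high <- round(cfg$frac_high * cfg$n_pre)
  p_hi <- cfg$rate_high / 1000 * cfg$dt
  p_lo <- cfg$rate_low / 1000 * cfg$dt
  n_steps * (n_high * p_hi * (1 - p_hi) +
               (cfg$n_pre - n_high) * p_lo * (1 - p_lo))
}
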