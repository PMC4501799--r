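#' Presynaptic state for a set of synapses
#'
#' Per-synapse state of the release machinery: weight (peak EPSC amplitude,
#' pA), the active and recycling vesicle pools (their sum is conserved at
#' `pool_total`), residual calcium (in units of release rate per ms) and the
#' release-mode fractions.
#'
#' @param n number of synapses.
#' @param weight initial weight(s), pA.
#' @param fractions a [release_fractions()] vector.
#' @param config a [vtdp_config()].
#' @return A list of class `synapse_state` with numeric vectors `w`,
#'   `pool_active`, `pool_recycling`, `ca` and the `fractions`.
#' @export
synapse_state <- function(n = 1L, weight = 1, fractions = release_fractions(),
                          config = vtdp_config()) {
  stopifnot(n >= 1L)
  st <- list(w = rep_len(weight, n),
             pool_active = rep(config$pool_total, n),
             pool_recycling = rep(0, n),
             ca = rep(0, n),
             fractions = fractions,
             pool_total = config$pool_total)
  structure(st, class = "synapse_state")
}

#' Poisson presynaptic spike train
#'
#' Bernoulli approximation of a Poisson process on the integration grid: a
#' neuron firing at rate r emits at most one spike per step, with per-step
#' probability `r * dt` (r converted to per-ms).
#'
#' @param rate_hz firing rate in Hz.
#' @param duration_ms train length in ms.
#' @param dt step in ms.
#' @return Numeric vector of spike times (ms, end-of-step convention).
#' @examples
#' set.seed(1)
#' tr <- generate_spikes(8, 10000)
#' length(tr) / 10  # about 8 Hz
#' @export
generate_spikes <- function(rate_hz, duration_ms, dt = 1) {
  if (rate_hz < 0) stop("rate must be non-negative", call. = FALSE)
  p <- rate_hz / 1000 * dt
  if (p > 1) stop("rate * dt exceeds one spike per step; decrease dt", call. = FALSE)
  n <- floor(duration_ms / dt)
  if (p == 0 || n == 0) return(numeric())
  which(runif(n) < p) * dt
}

#' Residual-calcium step
#'
#' Exponential decay with time constant `tau_ca`; a presynaptic action
#' potential adds an increment sized so that the discrete-time integral of
#' the asynchronous release rate following one spike equals exactly
#' `n_ves` vesicles (the calibration that puts all three release modes on an
#' equal mean-rate footing).
#'
#' @param ca residual calcium (per-ms rate units), vectorized.
#' @param spiked logical, whether each neuron spiked this step.
#' @param dt step (ms).
#' @param tau_ca calcium decay constant (ms).
#' @param n_ves vesicles per action potential.
#' @return Updated calcium vector.
#' @export
step_calcium <- function(ca, spiked, dt = 1, tau_ca = 100, n_ves = 4) {
  if (tau_ca <= 0) stop("tau_ca must be positive", call. = FALSE)
  d <- exp(-dt / tau_ca)
  ca * d + ifelse(spiked, calcium_jump(dt, tau_ca, n_ves), 0)
}

#' @rdname step_calcium
#' @export
calcium_jump <- function(dt = 1, tau_ca = 100, n_ves = 4) {
  n_ves * (1 - exp(-dt / tau_ca)) / dt
}

#' Expected vesicle releases per step, by mode
#'
#' Spontaneous release is a constant-rate process scaled by the nominal
#' population mean firing rate `r_m`; asynchronous release follows residual
#' calcium; synchronous release is spike-triggered with an expected count of
#' `n_ves * xi_seve * pool_active / pool_total` per action potential. All
#' three means share the pool-availability factor, so at matched drive the
#' three modes have equal long-run release rates.
#'
#' @param fractions a [release_fractions()] vector.
#' @param ca residual calcium (per ms), vectorized over synapses.
#' @param spiked logical vector, presynaptic spike this step.
#' @param pool_active active-pool size, vectorized.
#' @param pool_total total pool per synapse.
#' @param r_m_hz population mean firing rate (Hz).
#' @param n_ves vesicles per action potential.
#' @param dt step (ms).
#' @return List of numeric vectors `sve`, `aeve`, `seve` (expected counts for
#'   the step).
#' @examples
#' # pure spontaneous release at the default rate pattern, full pool:
#' m <- release_means(release_fractions(0, 0), ca = 0, spiked = FALSE,
#'                    pool_active = 100, pool_total = 100, r_m_hz = 4.8)
#' m$sve  # 4 * 0.0048 = 0.0192 expected vesicles per ms
#' @export
release_means <- function(fractions, ca, spiked, pool_active,
                          pool_total = 100, r_m_hz = 4.8, n_ves = 4, dt = 1) {
  if (any(pool_active < 0)) stop("active pool must be non-negative", call. = FALSE)
  avail <- pool_active / pool_total
  list(sve = n_ves * (r_m_hz / 1000) * fractions[["sve"]] * avail * dt,
       aeve = ca * fractions[["aeve"]] * avail * dt,
       seve = ifelse(spiked, n_ves * fractions[["seve"]] * avail, 0))
}

#' Sample vesicle release counts
#'
#' Draws per-mode Poisson counts at the given means; if an active-pool vector
#' is supplied, the total per synapse is capped at the available vesicles
#' (spontaneous, then asynchronous, then synchronous vesicles are kept, in
#' that order, when the cap binds).
#'
#' @param means list as returned by [release_means()].
#' @param pool_active optional active-pool sizes for capping.
#' @return List of integer vectors `sve`, `aeve`, `seve` and `total`.
#' @export
sample_releases <- function(means, pool_active = NULL) {
  if (any(unlist(means) < 0)) stop("release means must be non-negative", call. = FALSE)
  n <- length(means$sve)
  out <- list(sve = rpois(n, means$sve),
              aeve = rpois(n, means$aeve),
              seve = rpois(n, means$seve))
  if (!is.null(pool_active)) {
    cap <- floor(pool_active)
    keep_s <- pmin(out$sve, cap)
    keep_a <- pmin(out$aeve, pmax(cap - keep_s, 0))
    keep_e <- pmin(out$seve, pmax(cap - keep_s - keep_a, 0))
    out <- list(sve = keep_s, aeve = keep_a, seve = keep_e)
  }
  out$total <- out$sve + out$aeve + out$seve
  out
}

#' Vesicle pool recovery
#'
#' Exocytosed vesicles move from the active to the recycling pool and return
#' with time constant `tau_rec`; the sum of the two pools is conserved. The
#' update uses the exact exponential solution on the step.
#'
#' @param pool_active active-pool sizes.
#' @param pool_total total pool per synapse.
#' @param dt step (ms).
#' @param tau_rec recycling time constant (ms).
#' @return Updated active-pool vector.
#' @examples
#' recover_pool(0, 100, dt = 800, tau_rec = 800)  # 100 * (1 - exp(-1))
#' @export
recover_pool <- function(pool_active, pool_total = 100, dt = 1, tau_rec = 800) {
  if (tau_rec <= 0) stop("tau_rec must be positive", call. = FALSE)
  pool_total - (pool_total - pool_active) * exp(-dt / tau_rec)
}
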