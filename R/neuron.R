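#' Summed excitatory postsynaptic current
#'
#' Each released vesicle contributes a current `w * exp(-(t - t_ves) /
#' tau_alpha)` from its release time until `t_ves + t_window`, after which
#' the contribution is dropped (at the default constants less than 0.2% of
#' the initial current remains at truncation).
#'
#' @param release_times vesicle release times (ms), all `<= t`.
#' @param weights synaptic weight (pA) carried by each release.
#' @param t evaluation time (ms).
#' @param tau_alpha EPSC decay constant (ms).
#' @param t_window truncation window (ms).
#' @return Total current in pA.
#' @examples
#' epsc_current(c(0, 3), c(10, 10), t = 3)  # 10 * (exp(-1) + 1)
#' @export
epsc_current <- function(release_times, weights, t, tau_alpha = 3, t_window = 20) {
  if (length(release_times) == 0L) return(0)
  if (any(release_times > t)) stop("release times must not exceed t", call. = FALSE)
  lag <- t - release_times
  live <- lag < t_window
  sum(weights[live] * exp(-lag[live] / tau_alpha))
}

#' Postsynaptic neuron state
#'
#' Membrane potential and adaptive spike threshold of one or more leaky
#' integrate-and-fire neurons.
#'
#' @param n number of neurons.
#' @param config a [vtdp_config()].
#' @return List of class `postsynaptic_state` with vectors `v` (mV), `theta`
#'   (mV) and `spike_times` (list of numeric vectors).
#' @export
postsynaptic_state <- function(n = 1L, config = vtdp_config()) {
  structure(list(v = rep(config$v_rest, n),
                 theta = rep(config$theta_rest, n),
                 spike_times = rep(list(numeric()), n)),
            class = "postsynaptic_state")
}

#' One integration step of the adaptive-threshold LIF neuron
#'
#' The membrane relaxes toward `v_rest + I * tau_mem / c_mem` and the
#' threshold toward `theta_rest`, both with exact exponential factors for the
#' step (the input current is held constant across the step). If the membrane
#' reaches the threshold (ties count as spikes) the neuron fires, the
#' threshold resets to `theta_max` and the membrane to `v_rest`; the high
#' post-spike threshold supplies refractoriness.
#'
#' @param state a [postsynaptic_state()].
#' @param current input current (pA), scalar or per-neuron vector.
#' @param dt step (ms).
#' @param config a [vtdp_config()].
#' @param t current time (ms), recorded for spikes.
#' @return Updated state with logical attribute-free field `spiked`.
#' @export
lif_step <- function(state, current, dt = 1, config = vtdp_config(), t = NA_real_) {
  if (any(!is.finite(state$v)) || any(!is.finite(current)))
    stop("non-finite membrane potential or current", call. = FALSE)
  v_inf <- config$v_rest + current * config$tau_mem / config$c_mem
  dm <- exp(-dt / config$tau_mem)
  dth <- exp(-dt / config$tau_theta)
  v <- v_inf + (state$v - v_inf) * dm
  theta <- config$theta_rest + (state$theta - config$theta_rest) * dth
  spiked <- v >= theta
  v[spiked] <- config$v_rest
  theta[spiked] <- config$theta_max
  if (any(spiked) && !is.na(t))
    for (j in which(spiked))
      state$spike_times[[j]] <- c(state$spike_times[[j]], t)
  state$v <- v
  state$theta <- theta
  state$spiked <- spiked
  state
}
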