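#' Vesicle-timing dependent plasticity rule
#'
#' Pair-based Hebbian rule in which the presynaptic timing variable is the
#' vesicle release time. For a vesicle preceding a postsynaptic spike by
#' `delta_s > 0` the weight potentiates by
#' `lambda * w0^(1-mu) * w^mu * exp(-delta_s/tau)` (weight-dependent,
#' concave); for a vesicle following a spike (`delta_s < 0`) it depresses by
#' `-lambda * alpha * w * exp(-|delta_s|/tau)` (multiplicative).
#'
#' @param lambda learning amplitude.
#' @param mu potentiation weight-dependence exponent, in (0, 1).
#' @param alpha depression asymmetry factor.
#' @param tau pairing time constant (ms).
#' @param w0 reference weight (pA), conventionally `w0_frac` times the mean
#'   weight after spontaneous-release equilibration.
#' @param pairing_cutoff maximal `|delta_s|` considered (ms); beyond seven
#'   time constants the exponential is below 1e-3.
#' @return List of class `plasticity_rule`.
#' @export
plasticity_rule <- function(lambda = 0.1, mu = 0.4, alpha = 0.11, tau = 20,
                            w0 = 1, pairing_cutoff = 7 * tau) {
  if (lambda <= 0 || alpha <= 0 || tau <= 0 || w0 <= 0)
    stop("lambda, alpha, tau and w0 must be positive", call. = FALSE)
  if (mu <= 0 || mu >= 1) stop("mu must lie in (0, 1)", call. = FALSE)
  structure(list(lambda = lambda, mu = mu, alpha = alpha, tau = tau,
                 w0 = w0, pairing_cutoff = pairing_cutoff),
            class = "plasticity_rule")
}

#' Weight increment for one vesicle/post-spike pair
#'
#' @param w current weight(s), non-negative.
#' @param delta_s postsynaptic spike time minus vesicle release time (ms);
#'   positive means the vesicle preceded the spike.
#' @param rule a [plasticity_rule()].
#' @return Weight increment (same length as `w`/`delta_s`).
#' @examples
#' r <- plasticity_rule(w0 = 10)
#' vtdp_update(10, 1e-9, r)    # ~ lambda * w0
#' vtdp_update(50, -20, r)     # -lambda * alpha * 50 * exp(-1)
#' @export
vtdp_update <- function(w, delta_s, rule) {
  if (any(w < 0)) stop("weights must be non-negative", call. = FALSE)
  n <- max(length(w), length(delta_s))
  w <- rep_len(w, n)
  delta_s <- rep_len(delta_s, n)
  dec <- exp(-abs(delta_s) / rule$tau)
  out <- numeric(n)
  pos <- delta_s > 0
  neg <- delta_s < 0
  out[pos] <- rule$lambda * rule$w0^(1 - rule$mu) * w[pos]^rule$mu * dec[pos]
  out[neg] <- -rule$lambda * rule$alpha * w[neg] * dec[neg]
  out
}

#' Nearest-neighbour vesicle/spike pairing
#'
#' Pairs each vesicle with its nearest preceding and nearest following
#' postsynaptic spike (when within the pairing cutoff) and returns one row
#' per realized pair. A vesicle landing exactly on a spike time is treated as
#' causally preceding it with `delta_s = tie_delta`.
#'
#' @param vesicle_times release times (ms).
#' @param post_times postsynaptic spike times (ms), sorted.
#' @param cutoff maximal `|delta_s|` (ms).
#' @param tie_delta `delta_s` assigned to exact ties (ms).
#' @return Data frame with columns `vesicle` (index into `vesicle_times`)
#'   and `delta_s`.
#' @export
pair_events <- function(vesicle_times, post_times, cutoff = 140, tie_delta = 0.5) {
  if (length(vesicle_times) == 0L || length(post_times) == 0L)
    return(data.frame(vesicle = integer(), delta_s = numeric()))
  post_times <- sort(post_times)
  idx_after <- findInterval(vesicle_times, post_times, left.open = TRUE) + 1L
  rows <- list()
  # nearest following spike (potentiation side, includes exact ties)
  has_next <- idx_after <= length(post_times)
  if (any(has_next)) {
    ds <- post_times[pmin(idx_after, length(post_times))] - vesicle_times
    ds[ds == 0] <- tie_delta
    keep <- has_next & ds <= cutoff
    rows$ltp <- data.frame(vesicle = which(keep), delta_s = ds[keep])
  }
  # nearest preceding spike (depression side, strict precedence)
  idx_before <- findInterval(vesicle_times, post_times, left.open = TRUE)
  has_prev <- idx_before >= 1L
  if (any(has_prev)) {
    ds <- post_times[pmax(idx_before, 1L)] - vesicle_times
    keep <- has_prev & -ds <= cutoff
    rows$ltd <- data.frame(vesicle = which(keep), delta_s = ds[keep])
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(vesicle = integer(), delta_s = numeric())
  rownames(out) <- NULL
  out
}

#' Apply the pair rule over an event window
#'
#' Accumulates one [vtdp_update()] term per vesicle/spike pair found by
#' [pair_events()], applying updates in time order of the pairing events,
#' then clips weights to the hard bounds `[0, w_max]`.
#'
#' @param releases data frame with columns `time_ms` and `synapse` (index
#'   into `weights`).
#' @param post_times postsynaptic spike times (ms).
#' @param weights per-synapse weights (pA).
#' @param rule a [plasticity_rule()].
#' @param w_max upper hard bound (pA).
#' @return Updated weight vector.
#' @export
pair_and_apply <- function(releases, post_times, weights, rule, w_max = Inf) {
  if (nrow(releases) == 0L || length(post_times) == 0L) return(weights)
  if (is.unsorted(releases$time_ms)) releases <- releases[order(releases$time_ms), ]
  pairs <- pair_events(releases$time_ms, post_times, cutoff = rule$pairing_cutoff)
  if (nrow(pairs) == 0L) return(weights)
  # a pair takes effect when its later event occurs
  eff <- pmax(releases$time_ms[pairs$vesicle],
              releases$time_ms[pairs$vesicle] + pairs$delta_s)
  ord <- order(eff)
  for (k in ord) {
    syn <- releases$synapse[pairs$vesicle[k]]
    wnew <- weights[syn] + vtdp_update(weights[syn], pairs$delta_s[k], rule)
    weights[syn] <- min(max(wnew, 0), w_max)
  }
  weights
}

#' Homeostatic synaptic scaling step
#'
#' Multiplicative scaling of all weights converging on a neuron toward its
#' target firing rate: `dw = (r_m - r_j) * w * dt / tau_h`, with rates in Hz
#' and times in seconds.
#'
#' @param weights weights onto one postsynaptic neuron (pA).
#' @param r_j the neuron's recent firing rate (Hz).
#' @param r_m target rate (Hz).
#' @param dt_s elapsed time covered by this update (s).
#' @param tau_h_s homeostatic time constant (s).
#' @return Updated weight vector.
#' @examples
#' homeostatic_step(1, r_j = 2.4, r_m = 4.8, dt_s = 1, tau_h_s = 100)
#' @export
homeostatic_step <- function(weights, r_j, r_m, dt_s, tau_h_s = 100) {
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  fac <- max(0, 1 + (r_m - r_j) * dt_s / tau_h_s)
  weights * fac
}

#' Running firing-rate estimate from recent spikes
#'
#' The homeostatic controller's rate signal: once twelve spikes exist, the
#' rate is twelve divided by the time elapsed since the twelfth-most-recent
#' spike; before that it is the cumulative spike count over elapsed time
#' (zero at the start), which lets the controller engage from a silent cold
#' start.
#'
#' @param spike_times the neuron's spike times so far (ms).
#' @param t current time (ms).
#' @param t_start observation start (ms).
#' @param n_window running-window spike count (12).
#' @return Rate in Hz.
#' @export
running_rate <- function(spike_times, t, t_start = 0, n_window = 12L) {
  k <- length(spike_times)
  if (k >= n_window) {
    t12 <- spike_times[k - n_window + 1L]
    return(n_window / ((t - t12) / 1000))
  }
  if (t <= t_start) return(0)
  k / ((t - t_start) / 1000)
}
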