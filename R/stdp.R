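#' Pairing protocol for the plasticity-versus-timing curve
#'
#' Defines the classical induction experiment rendered in vesicle terms: for
#' each offset `delta_t = t_post - t_pre`, a presynaptic action potential
#' and a forced (clamped) postsynaptic spike are delivered `n_pairings`
#' times at `pairing_hz`; vesicles sampled from the active release modes
#' pair with the postsynaptic spikes through the vesicle-timing rule. With
#' release time-locked to the action potential the curve reproduces the
#' canonical antisymmetric form; with temporally diffuse release
#' (asynchronous mode, long calcium time constant) timing sensitivity is
#' lost — the immature form.
#'
#' @param delta_t_ms offsets (ms), both signs; positive = pre before post.
#' @param n_pairings pairings per offset.
#' @param pairing_hz pairing frequency (Hz); slow enough that consecutive
#'   pairings do not interact through the pairing window.
#' @param tau_ca calcium decay constant (ms) for the asynchronous mode.
#' @param fractions a [release_fractions()]; default pure asynchronous.
#' @return List of class `stdp_protocol`.
#' @export
stdp_protocol <- function(delta_t_ms = c(-80, -60, -40, -20, -10, -5,
                                         5, 10, 20, 40, 60, 80),
                          n_pairings = 50, pairing_hz = 1, tau_ca = 100,
                          fractions = release_fractions(xi_aeve = 1)) {
  if (n_pairings < 1) stop("n_pairings must be at least 1", call. = FALSE)
  if (any(delta_t_ms == 0)) stop("delta_t offsets must be non-zero", call. = FALSE)
  period_ms <- 1000 / pairing_hz
  if (period_ms < 4 * max(abs(delta_t_ms)))
    stop("pairing period must be much longer than the pairing window",
         call. = FALSE)
  structure(list(delta_t_ms = delta_t_ms, n_pairings = n_pairings,
                 pairing_hz = pairing_hz, tau_ca = tau_ca,
                 fractions = fractions),
            class = "stdp_protocol")
}

#' Simulated plasticity-versus-timing curve
#'
#' Runs the pairing protocol for each offset on one synapse. Within a trial
#' the presynaptic action potential triggers synchronous release and a
#' residual-calcium transient driving asynchronous release (the calcium
#' carries over between trials); spontaneous release, when enabled, runs at
#' a constant rate scaled by the pairing frequency. Every vesicle pairs with
#' its nearest preceding and following postsynaptic spike; the weight
#' evolves sequentially under the vesicle-timing rule with the standard hard
#' bounds.
#'
#' @param protocol an [stdp_protocol()].
#' @param config a [vtdp_config()]; supplies the rule constants, `dt` and
#'   the per-action-potential vesicle count.
#' @param w_start starting weight (pA); the rule reference is
#'   `w0_frac * w_start` and the upper bound `weight_upper_mult * w_start`.
#' @param pools use finite vesicle pools (default clamps them full, as in
#'   the low-rate induction experiments the protocol emulates).
#' @return Data frame with one row per offset: `delta_t_ms`, `dw_total`
#'   (pA), `dw_pct` (percent of `w_start`), `mean_per_pairing`,
#'   `sd_per_pairing`, `n_vesicles`.
#' @export
stdp_curve <- function(protocol, config = vtdp_config(), w_start = 100,
                       pools = FALSE) {
  stopifnot(inherits(protocol, "stdp_protocol"))
  dt <- config$dt
  period <- 1000 / protocol$pairing_hz
  steps <- round(period / dt)
  rule <- plasticity_rule(lambda = config$lambda_ltp, mu = config$mu,
                          alpha = config$alpha_ltd, tau = config$tau_stdp,
                          w0 = config$w0_frac * w_start,
                          pairing_cutoff = 7 * config$tau_stdp)
  w_max <- config$weight_upper_mult * w_start
  fr <- protocol$fractions
  n_ves <- config$n_ves_per_ap
  decay <- exp(-dt / protocol$tau_ca)
  jump <- n_ves * (1 - decay) / dt
  sve_rate <- n_ves * (protocol$pairing_hz / 1000) * fr[["sve"]] * dt
  t_pre_in_trial <- period / 2

  out <- lapply(protocol$delta_t_ms, function(dtt) {
    w <- w_start
    ca <- 0
    pa <- config$pool_total
    per_pairing <- numeric(protocol$n_pairings)
    n_ves_tot <- 0L
    for (p in seq_len(protocol$n_pairings)) {
      t0 <- (p - 1) * period
      t_pre <- t0 + t_pre_in_trial
      t_post <- t_pre + dtt
      # calcium trace across the trial (decay from carry-in, jump at t_pre)
      tt <- t0 + seq_len(steps) * dt
      ca_tr <- ca * decay^seq_len(steps)
      after <- tt >= t_pre
      ca_tr[after] <- ca_tr[after] + jump * decay^(seq_len(steps)[after] -
                                                    which(after)[1L])
      avail <- if (pools) pa / config$pool_total else 1
      mu_t <- ca_tr * fr[["aeve"]] * dt * avail + sve_rate * avail
      counts <- rpois(steps, mu_t)
      if (fr[["seve"]] > 0)
        counts[which(after)[1L]] <- counts[which(after)[1L]] +
          rpois(1, n_ves * fr[["seve"]] * avail)
      rel_idx <- which(counts > 0)
      w_before <- w
      if (length(rel_idx)) {
        rel <- data.frame(time_ms = rep(tt[rel_idx], counts[rel_idx]),
                          synapse = 1L)
        n_ves_tot <- n_ves_tot + nrow(rel)
        if (pools) pa <- max(pa - nrow(rel), 0)
        w <- pair_and_apply(rel, t_post, w, rule, w_max = w_max)
      }
      if (pools) pa <- recover_pool(pa, config$pool_total, dt = period,
                                    tau_rec = config$tau_rec)
      ca <- ca_tr[steps]
      per_pairing[p] <- w - w_before
    }
    data.frame(delta_t_ms = dtt, dw_total = w - w_start,
               dw_pct = 100 * (w - w_start) / w_start,
               mean_per_pairing = mean(per_pairing),
               sd_per_pairing = sd(per_pairing),
               n_vesicles = n_ves_tot)
  })
  do.call(rbind, out)
}

#' Timing-sensitivity index of a plasticity curve
#'
#' Difference between the weight change at `+probe_ms` and at `-probe_ms` —
#' near zero for the timing-insensitive immature curve, large for the mature
#' antisymmetric curve.
#'
#' @param curve data frame from [stdp_curve()].
#' @param probe_ms offset magnitude to compare at (must be in the curve's
#'   grid on both sides).
#' @return Scalar index in percent-of-starting-weight units.
#' @export
timing_sensitivity <- function(curve, probe_ms = 10) {
  up <- curve$dw_pct[curve$delta_t_ms == probe_ms]
  dn <- curve$dw_pct[curve$delta_t_ms == -probe_ms]
  if (length(up) != 1L || length(dn) != 1L)
    stop("probe offset not present on both sides of the curve", call. = FALSE)
  up - dn
}

#' Maturation series of the timing-sensitivity index
#'
#' Runs [stdp_curve()] for a list of calcium time constants (long constants
#' emulate the immature, temporally diffuse release; short constants the
#' mature, stimulus-locked release) and reports the index per constant.
#'
#' @param tau_ca_ms calcium constants (ms), e.g. `c(1000, 7, 2)`.
#' @param config a [vtdp_config()].
#' @param probe_ms index probe offset (ms).
#' @param ... passed to [stdp_protocol()].
#' @return Data frame `tau_ca_ms`, `sensitivity`, plus the curves as an
#'   attribute `curves`.
#' @export
stdp_maturation <- function(tau_ca_ms = c(1000, 7, 2), config = vtdp_config(),
                            probe_ms = 10, ...) {
  curves <- lapply(tau_ca_ms, function(tc)
    stdp_curve(stdp_protocol(tau_ca = tc, ...), config = config))
  idx <- vapply(curves, timing_sensitivity, numeric(1), probe_ms = probe_ms)
  structure(data.frame(tau_ca_ms = tau_ca_ms, sensitivity = idx),
            curves = curves)
}
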