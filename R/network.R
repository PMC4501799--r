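#' Release-fraction switch schedule
#'
#' Piecewise schedule of the release-mode fractions over simulated time,
#' used to express the developmental switch from spontaneous to evoked
#' exocytosis (abrupt or gradual).
#'
#' @param times_ms breakpoint times (ms), sorted, first at the run start.
#' @param fractions list of [release_fractions()] (one per breakpoint) or a
#'   single fractions vector for a constant schedule.
#' @param interpolation `"step"` (hold until the next breakpoint) or
#'   `"linear"` (interpolate each fraction; complements are preserved because
#'   the three fractions are interpolated jointly).
#' @return List of class `switch_schedule`.
#' @examples
#' # spontaneous-only for 100 s, then an abrupt switch to synchronous evoked
#' sched <- switch_schedule(c(0, 100e3),
#'                          list(release_fractions(0, 0), release_fractions(0, 1)))
#' @export
switch_schedule <- function(times_ms = 0, fractions = release_fractions(),
                            interpolation = c("step", "linear")) {
  interpolation <- match.arg(interpolation)
  if (inherits(fractions, "vtdp_fractions")) fractions <- list(fractions)
  stopifnot(length(times_ms) == length(fractions))
  if (is.unsorted(times_ms, strictly = TRUE))
    stop("schedule breakpoints must be strictly increasing", call. = FALSE)
  mat <- do.call(rbind, lapply(fractions, function(f) {
    if (!inherits(f, "vtdp_fractions")) f <- do.call(release_fractions, as.list(f))
    as.numeric(f)
  }))
  colnames(mat) <- c("sve", "aeve", "seve")
  if (any(abs(rowSums(mat) - 1) > 1e-12))
    stop("fractions must sum to one at every breakpoint", call. = FALSE)
  structure(list(times_ms = times_ms, fractions = mat,
                 interpolation = interpolation),
            class = "switch_schedule")
}

#' @rdname switch_schedule
#' @param schedule a `switch_schedule`.
#' @param t_ms times (ms) at which to evaluate the schedule.
#' @return `xi_at()`: matrix with columns `sve`, `aeve`, `seve`.
#' @export
xi_at <- function(schedule, t_ms) {
  bp <- schedule$times_ms
  idx <- pmax(findInterval(t_ms, bp), 1L)
  out <- schedule$fractions[idx, , drop = FALSE]
  if (schedule$interpolation == "linear" && length(bp) > 1L) {
    nxt <- pmin(idx + 1L, length(bp))
    span <- bp[nxt] - bp[idx]
    frac <- ifelse(span > 0, pmin((t_ms - bp[idx]) / span, 1), 0)
    out <- out * (1 - frac) + schedule$fractions[nxt, , drop = FALSE] * frac
  }
  rownames(out) <- NULL
  out
}

#' Initialize the feed-forward network
#'
#' Builds the full network state: `n_pre` Poisson presynaptic neurons onto
#' `n_post` integrate-and-fire neurons, all-to-all (or masked) connectivity,
#' uniform small initial weights, full vesicle pools and resting membranes.
#' A fixed fraction of the presynaptic neurons (the "high-rate group") fires
#' at `rate_high`, the rest at `rate_low`.
#'
#' @param config a [vtdp_config()].
#' @param init_weight initial weight (pA) or an `n_pre x n_post` matrix.
#' @param conn optional logical/0-1 connectivity matrix (`n_pre x n_post`).
#' @return List of class `vtdp_network`. The high-rate group occupies the
#'   first `frac_high * n_pre` presynaptic indices; per-neuron nominal rates
#'   are in `$rates_hz`.
#' @export
network_init <- function(config = vtdp_config(), init_weight = 1, conn = NULL) {
  n_pre <- config$n_pre; n_post <- config$n_post
  n_high <- round(config$frac_high * n_pre)
  rates <- c(rep(config$rate_high, n_high), rep(config$rate_low, n_pre - n_high))
  w <- if (is.matrix(init_weight)) init_weight else
    matrix(init_weight, n_pre, n_post)
  if (is.null(conn)) conn <- matrix(1L, n_pre, n_post) else
    conn <- matrix(as.integer(conn != 0), n_pre, n_post)
  w[conn == 0L] <- 0
  structure(list(
    w = w, conn = conn,
    pa = matrix(config$pool_total, n_pre, n_post),
    ca = rep(0, n_pre),
    v = rep(config$v_rest, n_post),
    theta = rep(config$theta_rest, n_post),
    rate_ms = rates / 1000,
    rates_hz = rates,
    high_group = seq_len(n_high),
    t = 0,
    last_post = rep(-1e18, n_post),
    epsc_buf = matrix(0, round(config$t_window / config$dt), n_post),
    spike_hist = matrix(0, 12, n_post),
    hist_pos = rep(0L, n_post),
    spike_cum = rep(0, n_post),
    homeo_t0 = 0,
    pending = matrix(0, 0, 4),
    w_bar0 = NA_real_,
    config = config
  ), class = "vtdp_network")
}

core_params <- function(config, w0, w_max, plasticity, homeostasis, pools,
                        log_events, snapshot_stride_steps) {
  r_m <- mean_input_rate(config)
  list(n_pre = as.integer(config$n_pre), n_post = as.integer(config$n_post),
       dt = config$dt, v_rest = config$v_rest, c_mem = config$c_mem,
       tau_mem = config$tau_mem, theta_rest = config$theta_rest,
       theta_max = config$theta_max, tau_theta = config$tau_theta,
       tau_ca = config$tau_ca, tau_rec = config$tau_rec,
       n_ves_per_ap = config$n_ves_per_ap, pool_total = config$pool_total,
       r_m_ms = r_m / 1000, tau_alpha = config$tau_alpha,
       t_window = config$t_window, lambda_ltp = config$lambda_ltp,
       mu = config$mu, alpha_ltd = config$alpha_ltd,
       tau_stdp = config$tau_stdp, w0 = w0, w_max = w_max,
       pairing_cutoff = 7 * config$tau_stdp,
       tau_h_s = config$tau_h, h_block = as.integer(round(100 / config$dt)),
       r_target_hz = r_m,
       plasticity_on = plasticity, homeostasis_on = homeostasis,
       pools_on = pools, log_events = log_events,
       snapshot_stride = as.integer(snapshot_stride_steps))
}

state_fields <- c("w", "conn", "pa", "ca", "v", "theta", "rate_ms", "t",
                  "last_post", "epsc_buf", "spike_hist", "hist_pos",
                  "spike_cum", "homeo_t0", "pending")

#' Run the vesicle-timing dependent plasticity simulation
#'
#' Advances the full network for `duration_ms` under a release-fraction
#' schedule: presynaptic Poisson spikes, per-mode vesicle release with
#' residual calcium and finite pools, EPSC summation, adaptive-threshold LIF
#' integration, nearest-neighbour vesicle/spike pairing with the
#' vesicle-timing plasticity rule, and blockwise homeostatic scaling.
#'
#' @param net a [network_init()] state (typically after [equilibrate()]).
#' @param schedule a [switch_schedule()]; times are relative to `net$t`.
#' @param duration_ms simulated duration (ms).
#' @param snapshot_stride_ms interval between weight snapshots (ms); 0
#'   disables snapshots.
#' @param plasticity,homeostasis,pools logical switches for the pair rule,
#'   homeostatic scaling and finite vesicle pools (pools clamped full when
#'   `FALSE`).
#' @param log_events record an event-level log (memory-heavy; short runs).
#' @param release set `FALSE` to abolish vesicle release entirely (all mode
#'   fractions forced to zero) while leaving homeostasis active — the
#'   no-transmission control.
#' @param w_max upper weight bound (pA); defaults to `weight_upper_mult`
#'   times the equilibrated mean weight when available, otherwise unbounded.
#' @return List of class `vtdp_run`: updated `net`, snapshot matrix
#'   (`synapse x time`, `NA` for absent synapses), `snap_times`, data frame
#'   `post_spikes`, per-second postsynaptic `rate_trace`, per-mode release
#'   totals, and optionally an event log.
#' @export
simulate_vtdp <- function(net, schedule, duration_ms,
                          snapshot_stride_ms = 1000,
                          plasticity = TRUE, homeostasis = TRUE, pools = TRUE,
                          log_events = FALSE, w_max = NULL, release = TRUE) {
  stopifnot(inherits(net, "vtdp_network"), inherits(schedule, "switch_schedule"))
  config <- net$config
  n_steps <- round(duration_ms / config$dt)
  if (n_steps < 1) stop("duration shorter than one step", call. = FALSE)
  if (is.null(w_max))
    w_max <- if (is.na(net$w_bar0)) Inf else config$weight_upper_mult * net$w_bar0
  w0 <- if (is.na(net$w_bar0)) config$w0_frac else config$w0_frac * net$w_bar0
  stride_steps <- round(snapshot_stride_ms / config$dt)
  par <- core_params(config, w0 = w0, w_max = w_max, plasticity = plasticity,
                     homeostasis = homeostasis, pools = pools,
                     log_events = log_events,
                     snapshot_stride_steps = stride_steps)
  xi <- xi_at(schedule, (seq_len(n_steps) - 1) * config$dt)
  if (!release) xi[] <- 0
  res <- vtdp_core(par, net[state_fields], xi)
  for (f in state_fields) net[[f]] <- res$state[[f]]
  post <- data.frame(time_ms = res$post_t, neuron = res$post_j)
  run <- list(net = net,
              snapshots = res$snapshots, snap_times = res$snap_times,
              post_spikes = post,
              rate_trace = rate_trace(post, net$t - duration_ms, net$t,
                                      config$n_post),
              release_by_mode = res$release_by_mode,
              duration_ms = duration_ms)
  if (log_events)
    run$event_log <- build_event_log(res$pre_spikes, res$events,
                                     res$post_t, res$post_j)
  structure(run, class = "vtdp_run")
}

# per-second postsynaptic firing rates (Hz), neurons x seconds
rate_trace <- function(post_spikes, t_start, t_end, n_post) {
  secs <- seq(t_start, t_end, by = 1000)
  if (length(secs) < 2) return(matrix(0, n_post, 0))
  counts <- matrix(0, n_post, length(secs) - 1)
  if (nrow(post_spikes)) {
    bin <- findInterval(post_spikes$time_ms, secs, left.open = TRUE,
                        rightmost.closed = TRUE)
    ok <- bin >= 1 & bin <= ncol(counts)
    for (k in which(ok))
      counts[post_spikes$neuron[k], bin[k]] <-
        counts[post_spikes$neuron[k], bin[k]] + 1
  }
  counts
}

#' Equilibrate the network under spontaneous release
#'
#' Runs the network with pure spontaneous exocytosis and homeostatic scaling
#' (the pair rule is inactive: its reference weight is defined only relative
#' to the weight scale this equilibration produces) until the trailing mean
#' postsynaptic rate is within `tol` of the target, then records the mean
#' equilibrated weight `w_bar0` that anchors the plasticity reference
#' `w0 = w0_frac * w_bar0` and the hard bounds.
#'
#' @param net a [network_init()] state.
#' @param tol relative tolerance on the trailing-window rate (0.05).
#' @param window_s trailing window (s).
#' @param max_duration_s give up after this much simulated time.
#' @param chunk_s simulated seconds per convergence check.
#' @return The equilibrated `vtdp_network` (with `w_bar0` set).
#' @export
equilibrate <- function(net, tol = 0.05, window_s = 20, max_duration_s = 400,
                        chunk_s = 10) {
  stopifnot(inherits(net, "vtdp_network"))
  if (all(net$w[net$conn == 1L] == 0))
    stop("all weights are zero: no drive, equilibration cannot converge",
         call. = FALSE)
  config <- net$config
  r_m <- mean_input_rate(config)
  sched <- switch_schedule(0, release_fractions(0, 0))
  recent <- numeric()   # per-second population rates
  elapsed <- 0
  while (elapsed < max_duration_s) {
    run <- simulate_vtdp(net, sched, chunk_s * 1000, snapshot_stride_ms = 0,
                         plasticity = FALSE, homeostasis = TRUE,
                         w_max = Inf)
    net <- run$net
    recent <- c(recent, colMeans(run$rate_trace))
    elapsed <- elapsed + chunk_s
    if (elapsed >= window_s) {
      trailing <- mean(tail(recent, window_s))
      if (abs(trailing - r_m) / r_m <= tol) {
        net$w_bar0 <- mean(net$w[net$conn == 1L])
        return(net)
      }
    }
  }
  trailing <- mean(tail(recent, window_s))
  stop(sprintf(paste0("equilibration did not converge within %g s ",
                      "(trailing rate %.3g Hz, target %.3g Hz)"),
               max_duration_s, trailing, r_m), call. = FALSE)
}

#' @export
print.vtdp_run <- function(x, ...) {
  cat("VTDP simulation run\n")
  cat(sprintf("  simulated %.1f s; %d postsynaptic spikes (%.2f Hz mean)\n",
              x$duration_ms / 1000, nrow(x$post_spikes),
              nrow(x$post_spikes) / (x$duration_ms / 1000) /
                x$net$config$n_post))
  rel <- x$release_by_mode
  cat(sprintf("  vesicles released: SVE %d, aEVE %d, sEVE %d\n",
              as.integer(rel[["SVE"]]), as.integer(rel[["aEVE"]]),
              as.integer(rel[["sEVE"]])))
  invisible(x)
}

#' Export run outputs as delimited text
#'
#' Writes weight snapshots (long form: `time_ms, pre_idx, post_idx, weight`),
#' the per-second rate trace, and (when logged) the event log to CSV files
#' in `dir`.
#'
#' @param run a `vtdp_run`.
#' @param dir output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
export_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(weights = file.path(dir, "weights.csv"),
             rates = file.path(dir, "rates.csv"))
  cfg <- run$net$config
  if (length(run$snap_times)) {
    idx <- expand.grid(pre_idx = seq_len(cfg$n_pre), post_idx = seq_len(cfg$n_post))
    long <- do.call(rbind, lapply(seq_along(run$snap_times), function(k)
      data.frame(time_ms = run$snap_times[k], idx, weight = run$snapshots[, k])))
    write.csv(long, paths[["weights"]], row.names = FALSE)
  }
  rt <- run$rate_trace
  write.csv(data.frame(second = rep(seq_len(ncol(rt)), each = nrow(rt)),
                       neuron = rep(seq_len(nrow(rt)), ncol(rt)),
                       rate_hz = as.vector(rt)),
            paths[["rates"]], row.names = FALSE)
  if (!is.null(run$event_log)) {
    paths[["events"]] <- file.path(dir, "events.csv")
    write_event_log(run$event_log, paths[["events"]])
  }
  invisible(paths)
}
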