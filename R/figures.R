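#' Scripted figure-level scenarios
#'
#' Desk-scale drivers that each run one of the headline experiments end to
#' end, write their outputs (CSV series, PDF plots, a JSON report of the
#' qualitative property checks attached to the scenario) and return the
#' report. Scenario ids:
#'
#' * `fig1` — synaptic competition: spontaneous-release baseline versus
#'   switches to asynchronous/synchronous evoked release; divergence factor
#'   and rate ordering.
#' * `fig2` — maintenance roles of spontaneous release: homogenization of a
#'   heterogeneous weight distribution, distribution broadening under evoked
#'   release, and homeostatic runaway to the weight ceiling when release is
#'   abolished.
#' * `fig3` — rate-model pattern imprinting from unimodal versus bimodal
#'   initial weights across the spontaneous/evoked balance.
#' * `fig4` — developmental schedule from expression profiles: learning-rate
#'   transient and rise-then-fall synaptic density.
#' * `fig5` — maturation of the pairing curve as release becomes
#'   time-locked.
#'
#' Durations are reduced relative to exploratory runs but large enough for
#' every attached property check; they can be scaled with `time_scale`.
#'
#' @param figure scenario id.
#' @param config a [vtdp_config()] (network scenarios).
#' @param seed master seed.
#' @param out_dir output directory.
#' @param time_scale multiplier on the scenario's simulated durations.
#' @return The report, a named list of property checks (`value`, `pass`),
#'   invisibly written to `report.json`.
#' @export
reproduce_figure <- function(figure = c("fig1", "fig2", "fig3", "fig4", "fig5"),
                             config = vtdp_config(), seed = 1L,
                             out_dir = tempfile("vtdp_fig"),
                             time_scale = 1) {
  figure <- tryCatch(match.arg(figure), error = function(e)
    stop("unknown figure id; valid ids: fig1, fig2, fig3, fig4, fig5",
         call. = FALSE))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(vtdp_streams(seed)[["spikes"]])
  report <- switch(figure,
                   fig1 = scenario_competition(config, out_dir, time_scale),
                   fig2 = scenario_maintenance(config, out_dir, time_scale),
                   fig3 = scenario_imprinting(out_dir, time_scale),
                   fig4 = scenario_development(config, out_dir, time_scale),
                   fig5 = scenario_maturation(config, out_dir, time_scale))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

check <- function(value, pass) list(value = value, pass = isTRUE(pass))

scenario_competition <- function(config, out_dir, ts) {
  net <- equilibrate(network_init(config))
  dur <- 150e3 * ts
  runs <- list(
    sve = simulate_vtdp(net, switch_schedule(0, release_fractions(0, 0)), dur),
    aeve = simulate_vtdp(net, switch_schedule(0, release_fractions(1, 0)), dur),
    seve = simulate_vtdp(net, switch_schedule(0, release_fractions(0, 1)), dur))
  div <- lapply(runs, function(r)
    divergence_series(r$snapshots, r$snap_times, net$high_group,
                      config$n_pre, config$n_post))
  ser <- do.call(rbind, lapply(names(div), function(m)
    cbind(mode = m, div[[m]]$series)))
  write.csv(ser, file.path(out_dir, "divergence.csv"), row.names = FALSE)
  grDevices::pdf(file.path(out_dir, "divergence.pdf"), width = 6, height = 4)
  graphics::matplot(div$sve$series$time_s,
                    cbind(div$sve$series$divergence, div$aeve$series$divergence,
                          div$seve$series$divergence),
                    type = "l", lty = 1, col = c("black", "darkgreen", "red"),
                    xlab = "time (s)", ylab = "divergence factor D(t)")
  graphics::legend("topleft", c("SVE", "aEVE", "sEVE"), lty = 1,
                   col = c("black", "darkgreen", "red"), bty = "n")
  grDevices::dev.off()
  rates <- vapply(div, `[[`, numeric(1), "max_rate")
  list(sve_divergence_flat = check(
         tail(div$sve$series$divergence[is.finite(div$sve$series$divergence)], 1),
         abs(log(tail(div$sve$series$divergence[
           is.finite(div$sve$series$divergence)], 1))) < log(1.25)),
       rate_ordering = check(as.list(rates),
                             rates[["sve"]] < rates[["aeve"]] &
                               rates[["aeve"]] < rates[["seve"]]))
}

scenario_maintenance <- function(config, out_dir, ts) {
  # uncorrelated activity: every presynaptic neuron at the population mean
  cfg_u <- vtdp_config(modifyList(unclass(config),
                                  list(rate_low = mean_input_rate(config),
                                       rate_high = mean_input_rate(config))))
  net0 <- equilibrate(network_init(cfg_u))
  # heterogeneous start: rescale weights to CV 0.5 around the same mean
  cv_target <- 0.5
  set_cv <- function(net) {
    f <- pmax(rnorm(length(net$w), 1, cv_target), 0.05)
    net$w <- net$w * matrix(f, nrow(net$w))
    net
  }
  dur <- 100e3 * ts
  sve <- simulate_vtdp(set_cv(net0), switch_schedule(0, release_fractions(0, 0)), dur)
  eve <- simulate_vtdp(set_cv(net0), switch_schedule(0, release_fractions(0, 1)), dur)
  cv <- data.frame(time_s = sve$snap_times / 1000,
                   sve = weight_cv_series(sve$snapshots),
                   eve = weight_cv_series(eve$snapshots))
  write.csv(cv, file.path(out_dir, "weight_cv.csv"), row.names = FALSE)
  none <- simulate_vtdp(net0, switch_schedule(0, release_fractions(0, 0)), dur,
                        release = FALSE)
  grDevices::pdf(file.path(out_dir, "weight_cv.pdf"), width = 6, height = 4)
  graphics::matplot(cv$time_s, cv[, c("sve", "eve")], type = "l", lty = 1,
                    col = c("black", "blue"), xlab = "time (s)",
                    ylab = "weight CV")
  graphics::legend("topright", c("SVE", "EVE"), lty = 1,
                   col = c("black", "blue"), bty = "n")
  grDevices::dev.off()
  w_end <- none$net$w[none$net$conn == 1L]
  w_cap <- cfg_u$weight_upper_mult * net0$w_bar0
  list(sve_homogenizes = check(tail(cv$sve, 1),
                               tail(cv$sve, 1) < cv$sve[1]),
       eve_broader_than_sve = check(
         c(sve = tail(cv$sve, 1), eve = tail(cv$eve, 1)),
         tail(cv$eve, 1) > tail(cv$sve, 1)),
       no_release_saturates = check(mean(w_end) / w_cap,
                                    all(w_end > 0.99 * w_cap)))
}

scenario_imprinting <- function(out_dir, ts) {
  dur <- 2e5 * ts
  uni <- imprint_experiment("unimodal", xi = 0, duration_s = dur)
  bim <- imprint_experiment("bimodal", xi = 0, duration_s = dur)
  sve <- imprint_experiment("unimodal", xi = 1, duration_s = dur)
  tr <- rbind(cbind(case = "unimodal_eve", uni$trajectory),
              cbind(case = "bimodal_eve", bim$trajectory),
              cbind(case = "unimodal_sve", sve$trajectory))
  write.csv(tr, file.path(out_dir, "pattern_match.csv"), row.names = FALSE)
  grDevices::pdf(file.path(out_dir, "pattern_match.pdf"), width = 6, height = 4)
  graphics::matplot(uni$trajectory$time_s / 1000,
                    cbind(uni$trajectory$match, bim$trajectory$match,
                          sve$trajectory$match),
                    type = "l", lty = 1, col = c("gray30", "gray70", "red"),
                    xlab = "time (ks)", ylab = "pattern match P")
  graphics::legend("bottomright",
                   c("unimodal start, EVE", "bimodal start, EVE", "SVE"),
                   lty = 1, col = c("gray30", "gray70", "red"), bty = "n")
  grDevices::dev.off()
  t_uni <- time_to_match(uni$trajectory)
  t_bim <- time_to_match(bim$trajectory)
  list(unimodal_reaches_match = check(max(uni$trajectory$match),
                                      max(uni$trajectory$match) >= 0.95),
       bimodal_slower = check(c(unimodal_s = t_uni, bimodal_s = t_bim),
                              t_bim > t_uni),
       sve_stores_nothing = check(max(abs(sve$trajectory$match)),
                                  max(sve$trajectory$match) < 0.2))
}

scenario_development <- function(config, out_dir, ts) {
  # start from diffuse partial connectivity so synaptogenesis has room
  conn <- matrix(runif(config$n_pre * config$n_post) < 0.5,
                 config$n_pre, config$n_post)
  net <- equilibrate(network_init(config, conn = conn))
  dev <- develop(net, acceleration = 1e6 / ts)
  write.csv(data.frame(age = dev$ages, dev$xi, density = dev$density),
            file.path(out_dir, "development.csv"), row.names = FALSE)
  write.csv(dev$learning, file.path(out_dir, "learning_rate.csv"),
            row.names = FALSE)
  grDevices::pdf(file.path(out_dir, "development.pdf"), width = 6, height = 6)
  graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  graphics::plot(dev$learning$time_s, dev$learning$learning_rate, type = "l",
                 xlab = "time (s)", ylab = "learning rate (1/s)")
  graphics::plot(dev$ages, dev$density, type = "l", xlab = "age (y)",
                 ylab = "synapse count")
  grDevices::dev.off()
  lam <- dev$learning$learning_rate
  lam <- lam[is.finite(lam)]
  k_peak <- which.max(lam)
  dens_peak <- which.max(dev$density)
  list(learning_rate_transient = check(
         max(lam), k_peak > 1 && k_peak < length(lam) &&
           mean(tail(lam, max(3, length(lam) %/% 10))) < max(lam) / 2),
       density_rises_then_falls = check(
         c(start = dev$density[1], peak = max(dev$density),
           end = tail(dev$density, 1)),
         max(dev$density) > dev$density[1] &&
           tail(dev$density, 1) < max(dev$density)))
}

scenario_maturation <- function(config, out_dir, ts) {
  mat <- stdp_maturation(config = config)
  curves <- attr(mat, "curves")
  all_curves <- do.call(rbind, Map(cbind, tau_ca_ms = mat$tau_ca_ms, curves))
  write.csv(all_curves, file.path(out_dir, "stdp_curves.csv"), row.names = FALSE)
  grDevices::pdf(file.path(out_dir, "stdp_curves.pdf"), width = 5, height = 8)
  graphics::par(mfrow = c(length(curves), 1), mar = c(4, 4, 2, 1))
  for (k in seq_along(curves))
    graphics::plot(curves[[k]]$delta_t_ms, curves[[k]]$dw_pct, type = "b",
                   xlab = "t_post - t_pre (ms)", ylab = "weight change (%)",
                   main = sprintf("tau_Ca = %g ms", mat$tau_ca_ms[k]))
  grDevices::dev.off()
  list(sensitivity_increases = check(
    as.list(setNames(mat$sensitivity, paste0("tau", mat$tau_ca_ms))),
    all(diff(mat$sensitivity) > 0)))
}
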