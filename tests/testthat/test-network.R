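test_that("identical configuration and seed reproduce a run exactly", {
  cfg <- small_config()
  sched <- switch_schedule(0, release_fractions(0.2, 0.3))
  run_once <- function() {
    set.seed(cfg$seed)
    net <- network_init(cfg, init_weight = 20)
    net$w_bar0 <- 20
    simulate_vtdp(net, sched, 5e3, snapshot_stride_ms = 500,
                  log_events = TRUE)
  }
  a <- run_once()
  b <- run_once()
  expect_identical(a$snapshots, b$snapshots)
  expect_identical(a$post_spikes, b$post_spikes)
  expect_identical(a$net$w, b$net$w)
  expect_identical(a$release_by_mode, b$release_by_mode)
  expect_identical(a$event_log, b$event_log)
  # and the event log is well formed: sorted streams, valid mode tags
  expect_silent(vtdp:::validate_event_log(a$event_log))
  expect_true(all(a$event_log$mode[a$event_log$stream == "release"] %in%
                    c("SVE", "aEVE", "sEVE")))
})

test_that("switch schedules interpolate fractions as requested", {
  fr0 <- release_fractions(0, 0)
  fr1 <- release_fractions(0, 1)
  step <- switch_schedule(c(0, 1000), list(fr0, fr1))
  expect_equal(xi_at(step, c(0, 999, 1000, 5000))[, "seve"], c(0, 0, 1, 1))
  lin <- switch_schedule(c(0, 1000), list(fr0, fr1), interpolation = "linear")
  mid <- xi_at(lin, 500)
  expect_equal(unname(mid[, "seve"]), 0.5)
  expect_equal(sum(mid), 1)
  expect_error(switch_schedule(c(1000, 0), list(fr0, fr1)), "increasing")
})

test_that("spontaneous-release equilibration reaches the target rate regime", {
  net <- eq_net()
  cfg <- net$config
  expect_gt(net$w_bar0, 0)
  # the converged state really does hold the target rate: freeze weights
  # (no plasticity/homeostasis) and measure 20 s
  run <- simulate_vtdp(net, const_schedule("sve"), 20e3,
                       plasticity = FALSE, homeostasis = FALSE)
  rate <- nrow(run$post_spikes) / 20 / cfg$n_post
  expect_lt(abs(rate - mean_input_rate(cfg)) / mean_input_rate(cfg), 0.12)
  # zero weights cannot converge
  expect_error(equilibrate(network_init(cfg, init_weight = 0)), "no drive")
})

test_that("the three release modes are normalized to equal mean rates", {
  net <- eq_net()
  cfg <- net$config
  dur <- 20e3
  expected <- cfg$n_ves_per_ap * mean_input_rate(cfg) / 1000 *
    cfg$n_pre * cfg$n_post * dur
  var_s <- pattern_spike_var(cfg, dur)
  totals <- vapply(c("sve", "aeve", "seve"), function(m) {
    set.seed(vtdp_streams(31L + match(m, c("sve", "aeve", "seve")))[["release"]])
    run <- simulate_vtdp(net, const_schedule(m), dur, pools = FALSE,
                         plasticity = FALSE, homeostasis = FALSE,
                         snapshot_stride_ms = 0)
    sum(run$release_by_mode)
  }, numeric(1))
  # spontaneous release has no spike coupling: plain Poisson band
  expect_lt(abs(totals[["sve"]] - expected), 3 * sqrt(expected))
  # evoked modes inherit the spike-count fluctuation across 10 shared targets
  band <- evoked_release_band(expected, var_s, cfg$n_ves_per_ap, cfg$n_post)
  expect_lt(abs(totals[["aeve"]] - expected), band)
  expect_lt(abs(totals[["seve"]] - expected), band)
})

test_that("finite pools strictly lower the realized release rate", {
  net <- eq_net()
  run_with <- function(pools) {
    set.seed(808)
    run <- simulate_vtdp(net, const_schedule("sve"), 10e3, pools = pools,
                         plasticity = FALSE, homeostasis = FALSE,
                         snapshot_stride_ms = 0)
    sum(run$release_by_mode)
  }
  full <- run_with(FALSE)
  depleted <- run_with(TRUE)
  expect_lt(depleted, full)
  # steady-state availability: release/recovery balance gives
  # pa/pc = 1 / (1 + n r_m tau_rec / pc)
  cfg <- net$config
  avail <- 1 / (1 + cfg$n_ves_per_ap * mean_input_rate(cfg) / 1000 *
                  cfg$tau_rec / cfg$pool_total)
  expect_equal(depleted / full, avail, tolerance = 0.02)
})

test_that("abolishing release drives every weight to the homeostatic ceiling", {
  net <- eq_net()
  cfg <- net$config
  set.seed(66)
  run <- simulate_vtdp(net, const_schedule("sve"), 100e3, release = FALSE,
                       snapshot_stride_ms = 0)
  w <- run$net$w[run$net$conn == 1L]
  cap <- cfg$weight_upper_mult * net$w_bar0
  expect_true(all(w > 0.999 * cap))
  expect_true(all(w <= cap + 1e-9))
  expect_equal(nrow(run$post_spikes), 0)  # no vesicles, no spikes
})

test_that("spontaneous release homogenizes a heterogeneous weight distribution", {
  net <- eq_net_uniform()
  set.seed(14)
  f <- pmax(rnorm(length(net$w), 1, 0.5), 0.05)
  net$w <- net$w * matrix(f, nrow(net$w))
  cv0 <- sd(net$w) / mean(net$w)
  expect_gt(cv0, 0.4)
  run <- simulate_vtdp(net, const_schedule("sve"), 100e3)
  cv <- weight_cv_series(run$snapshots)
  # monotone tightening on 50-second windows
  expect_lt(cv[50], cv0)
  expect_lt(cv[100], cv[50])
  expect_lt(cv[100], 0.25)
})

test_that("evoked release broadens the stationary weight distribution", {
  # uncorrelated activity at matched mean release rates: synchronous evoked
  # release produces a wider stationary distribution than spontaneous
  net <- eq_net_uniform()
  set.seed(15)
  sve <- simulate_vtdp(net, const_schedule("sve"), 80e3)
  eve <- simulate_vtdp(net, const_schedule("seve"), 80e3)
  cv_sve <- tail(weight_cv_series(sve$snapshots), 1)
  cv_eve <- tail(weight_cv_series(eve$snapshots), 1)
  expect_gt(cv_eve, cv_sve)
  sd_sve <- sd(sve$snapshots[, ncol(sve$snapshots)])
  sd_eve <- sd(eve$snapshots[, ncol(eve$snapshots)])
  expect_gt(sd_eve, sd_sve)
})
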