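test_that("the pair-rule increments match their closed forms", {
  r <- plasticity_rule(w0 = 10)
  # at w = w0 and vanishing positive lag the increment is lambda * w0
  expect_equal(vtdp_update(10, 1e-12, r), 0.1 * 10, tolerance = 1e-9)
  # depression at one time constant is multiplicative in w
  expect_equal(vtdp_update(37, -20, r), -0.1 * 0.11 * 37 * exp(-1),
               tolerance = 1e-12)
  expect_equal(vtdp_update(37, -20, r) / 37, -0.004047, tolerance = 1e-4)
  # multiplicative depression vanishes at zero weight
  expect_equal(vtdp_update(0, -5, r), 0)
  expect_error(vtdp_update(-1, 5, r), "non-negative")
  expect_error(plasticity_rule(mu = 1.4), "mu")
})

test_that("potentiation is increasing and concave in w, depression linear", {
  r <- plasticity_rule(w0 = 10)
  w <- seq(1, 100, by = 1)
  ltp <- vtdp_update(w, 5, r)
  ltd <- vtdp_update(w, -5, r)
  expect_true(all(diff(ltp) > 0))
  expect_true(all(diff(diff(ltp)) < 0))          # concave
  expect_equal(diff(ltd), rep(diff(ltd)[1], length(ltd) - 1),
               tolerance = 1e-9)                  # linear
  # direct evaluation against the formula on the grid
  expect_equal(ltp, r$lambda * r$w0^(1 - r$mu) * w^r$mu * exp(-5 / r$tau))
})

test_that("nearest-neighbour pairing selects the flanking postsynaptic spikes", {
  p <- pair_events(vesicle_times = 100, post_times = c(50, 105, 300))
  # one depression pair with the preceding spike, one potentiation pair with
  # the nearest following spike; the spike at 300 is not the nearest
  expect_equal(sort(p$delta_s), c(-50, 5))
  # exact tie counts as causal potentiation at half a step
  ptie <- pair_events(100, 100, tie_delta = 0.5)
  expect_equal(ptie$delta_s, 0.5)
  # outside the cutoff nothing pairs
  expect_equal(nrow(pair_events(100, 400, cutoff = 140)), 0)
  expect_equal(nrow(pair_events(numeric(), 10)), 0)
})

test_that("pair_and_apply reproduces the single-pair closed form and bounds", {
  r <- plasticity_rule(w0 = 5)
  w <- 100
  rel <- data.frame(time_ms = 95, synapse = 1L)
  out <- pair_and_apply(rel, post_times = 100, weights = w, rule = r)
  expect_equal(out - w, r$lambda * r$w0^(1 - r$mu) * w^r$mu * exp(-5 / r$tau),
               tolerance = 1e-12)
  # no postsynaptic spikes: unchanged
  expect_equal(pair_and_apply(rel, numeric(), w, r), w)
  # an update driving the weight above the bound lands exactly on the bound
  big <- plasticity_rule(lambda = 50, w0 = 5)
  expect_equal(pair_and_apply(rel, 100, w, big, w_max = 120), 120)
  # depression can never push a weight negative
  neg <- pair_and_apply(data.frame(time_ms = 105, synapse = 1L), 100,
                        0.001, plasticity_rule(lambda = 5, w0 = 5))
  expect_gte(neg, 0)
})

test_that("homeostatic scaling has the right fixed point and rate", {
  expect_equal(homeostatic_step(13, r_j = 4.8, r_m = 4.8, dt_s = 1), 13)
  # dw/dt = (4.8 - 2.4) * 1 / 100 = 0.024 per second at w = 1
  out <- homeostatic_step(1, r_j = 2.4, r_m = 4.8, dt_s = 1, tau_h_s = 100)
  expect_equal(out - 1, 0.024, tolerance = 1e-12)
  expect_equal(homeostatic_step(0, 1, 5, 1), 0)  # zero weights stay zero
  expect_error(homeostatic_step(-1, 1, 5, 1), "non-negative")
})

test_that("the running-rate estimator engages from a silent cold start", {
  expect_equal(running_rate(numeric(), t = 0), 0)
  expect_equal(running_rate(numeric(), t = 5000), 0)
  # before twelve spikes: cumulative count over elapsed time
  expect_equal(running_rate(c(1000, 2000), t = 4000), 2 / 4)
  # with twelve spikes at exactly 5 Hz the estimate uses the window
  spikes <- seq(200, by = 200, length.out = 12)
  expect_equal(running_rate(spikes, t = 2600), 12 / ((2600 - 200) / 1000))
})
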