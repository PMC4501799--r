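test_that("spike trains follow the per-step Bernoulli law", {
  expect_identical(generate_spikes(0, 1000), numeric())
  expect_error(generate_spikes(-1, 100), "non-negative")
  expect_error(generate_spikes(2000, 100, dt = 1), "decrease dt")
  # empirical rate of a 4 Hz train over 200 s within 3 binomial SEs
  set.seed(101)
  tr <- generate_spikes(4, 200e3)
  n_steps <- 200e3
  p <- 4 / 1000
  se <- sqrt(n_steps * p * (1 - p))
  expect_lt(abs(length(tr) - n_steps * p), 3 * se)
  expect_true(all(diff(tr) > 0))
})

test_that("residual calcium decays exactly and jumps by the calibrated increment", {
  # closed-form decay over one time constant
  ca <- step_calcium(0.04, spiked = FALSE, dt = 100, tau_ca = 100)
  expect_equal(ca, 0.04 * exp(-1), tolerance = 1e-9)
  # zero stays zero
  expect_equal(step_calcium(0, FALSE), 0)
  # per-spike jump: the discrete geometric sum of the release rate after one
  # isolated spike must integrate to n_ves vesicles (oracle: explicit sum)
  dt <- 1; tau <- 100; n_ves <- 4
  ca1 <- step_calcium(0, TRUE, dt, tau, n_ves)
  expect_equal(ca1, calcium_jump(dt, tau, n_ves))
  k <- 0:5000
  total <- sum(ca1 * exp(-k * dt / tau) * dt)
  expect_equal(total, n_ves, tolerance = 1e-9)
  # same identity at a short constant (the mature, tightly locked regime)
  ca2 <- step_calcium(0, TRUE, 1, 2, 4)
  expect_equal(sum(ca2 * exp(-(0:100) / 2)), 4, tolerance = 1e-9)
})

test_that("per-mode release means follow the release-rate law", {
  fr_sve <- release_fractions(0, 0)
  m <- release_means(fr_sve, ca = 0, spiked = FALSE, pool_active = 100,
                     pool_total = 100, r_m_hz = 4.8, n_ves = 4, dt = 1)
  expect_equal(m$sve, 4 * 0.0048 * 1)   # 0.0192 per step at full pool
  expect_equal(m$aeve, 0)
  expect_equal(m$seve, 0)
  # synchronous mode: one spike at full pool carries n_ves expected vesicles
  m2 <- release_means(release_fractions(0, 1), ca = 0, spiked = TRUE,
                      pool_active = 100)
  expect_equal(m2$seve, 4)
  # empty pool silences all three modes
  m3 <- release_means(release_fractions(0.3, 0.3), ca = 1, spiked = TRUE,
                      pool_active = 0)
  expect_equal(unlist(m3), c(sve = 0, aeve = 0, seve = 0))
  # depletion is monotone: any pool deficit lowers every mode's mean
  m4 <- release_means(release_fractions(0.3, 0.3), ca = 1, spiked = TRUE,
                      pool_active = 60)
  m5 <- release_means(release_fractions(0.3, 0.3), ca = 1, spiked = TRUE,
                      pool_active = 100)
  expect_true(all(unlist(m4) < unlist(m5)))
})

test_that("sampled release totals match Poisson expectations", {
  expect_equal(sample_releases(list(sve = 0, aeve = 0, seve = 0))$total, 0)
  set.seed(55)
  n <- 1e6
  draws <- sample_releases(list(sve = rep(0.0192, n), aeve = rep(0, n),
                                seve = rep(0, n)))
  expected <- 0.0192 * n
  expect_lt(abs(sum(draws$total) - expected), 3 * sqrt(expected))
  # cap at the available pool
  capped <- sample_releases(list(sve = 50, aeve = 50, seve = 50),
                            pool_active = 3)
  expect_lte(capped$total, 3)
  expect_error(sample_releases(list(sve = -1, aeve = 0, seve = 0)),
               "non-negative")
})

test_that("asynchronous release delivers n_ves vesicles per action potential", {
  # single synapse, pool clamped full, 1000 spikes at 1 Hz, tau_ca = 100 ms;
  # the calcium trace after each spike is analytic, so per-step means are
  # exact and only the Poisson draws are stochastic
  set.seed(77)
  dt <- 1; tau <- 100
  n_spikes <- 1000
  jump <- calcium_jump(dt, tau, 4)
  per_trial_mu <- jump * exp(-(0:999) * dt / tau) * dt  # 1 s between spikes
  counts <- rpois(n_spikes * 1000, rep(per_trial_mu, n_spikes))
  mean_per_spike <- sum(counts) / n_spikes
  se <- sqrt(4 / n_spikes)
  expect_lt(abs(mean_per_spike - 4), 3 * se)
})

test_that("pool recovery follows its closed form and conserves vesicles", {
  expect_equal(recover_pool(0, 100, dt = 800, tau_rec = 800),
               100 * (1 - exp(-1)), tolerance = 1e-9)
  expect_equal(recover_pool(100, 100), 100)  # fixed point
  # active + recycling is conserved by construction; recovery never
  # overshoots the total from any admissible state
  pa <- seq(0, 100, by = 5)
  out <- recover_pool(pa, 100, dt = 50, tau_rec = 800)
  expect_true(all(out >= pa & out <= 100))
  st <- synapse_state(3)
  expect_equal(st$pool_active + st$pool_recycling, rep(100, 3))
})
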