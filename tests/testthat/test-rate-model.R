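test_that("exocytosis-rate matrices have the prescribed structure", {
  set.seed(1)
  # pure evoked: exactly two distinct values, bimodal by presynaptic row
  r0 <- make_rates(n = 50, xi = 0)
  expect_setequal(unique(as.vector(r0$x)), c(0.8, 0.4))
  expect_true(all(r0$x[r0$pattern, ] == 0.8))
  expect_true(all(r0$x[-r0$pattern, ] == 0.4))
  # pure spontaneous: no row structure (group row-means statistically equal)
  r1 <- make_rates(n = 100, xi = 1)
  hi <- rowMeans(r1$x)[r1$pattern]
  lo <- rowMeans(r1$x)[-r1$pattern]
  expect_lt(abs(mean(hi) - mean(lo)), 3 * 0.05 / sqrt(100 * 20))
  # mixture identity holds entrywise
  r5 <- make_rates(n = 30, xi = 0.5)
  expect_equal(r5$x, 0.5 * r5$sve + 0.5 * r5$eve)
  expect_error(make_rates(10, xi = 2), "xi")
})

test_that("the competition step has the stated drive, scaling and fixed points", {
  # zero drive when every rate equals the column mean
  w <- matrix(0.5, 4, 4)
  x <- matrix(1, 4, 4)
  expect_equal(rate_step(w, x, dt_s = 1), w)
  # dw/dt = gamma * (x - xbar) * (w - w^2) = 1e-4 * 0.2 * 0.25 = 5e-6 per s
  x2 <- matrix(c(1.2, 0.8), 2, 1)         # column mean 1.0
  w2 <- matrix(0.5, 2, 1)
  out <- rate_step(w2, x2, dt_s = 1, gamma = 1e-4)
  expect_equal(out[1, 1] - 0.5, 1e-4 * 0.2 * (0.5 - 0.25), tolerance = 1e-9)
  expect_equal(out[2, 1] - 0.5, -1e-4 * 0.2 * 0.25, tolerance = 1e-9)
  # boundary values are fixed points of the soft-bound factor
  wb <- matrix(c(1, 0), 2, 1)
  expect_equal(rate_step(wb, x2, dt_s = 1000), wb)
  expect_error(rate_step(matrix(0.5, 2, 2), matrix(1, 3, 3)), "shape")
})

test_that("precomputed drive and coarse steps match the reference step", {
  set.seed(8)
  r <- make_rates(n = 20, xi = 0.3)
  w <- matrix(runif(400), 20, 20)
  pre <- rate_drive(r$x)
  expect_equal(rate_step(w, r$x, dt_s = 3),
               rate_step(w, r$x, dt_s = 3, precomp = pre))
  # the dynamics are slow enough that a 10x coarser Euler step is equivalent
  w1 <- w
  for (k in 1:100) w1 <- rate_step(w1, r$x, dt_s = 1, precomp = pre)
  w10 <- w
  for (k in 1:10) w10 <- rate_step(w10, r$x, dt_s = 10, precomp = pre)
  expect_equal(w1, w10, tolerance = 1e-6)
})

test_that("pattern match is signed, bounded and null for unrelated weights", {
  set.seed(2)
  x <- make_rates(n = 60, xi = 0)$x
  # weights proportional to rates, with mean-preserving noise smaller than
  # the bimodal gap
  w <- x / max(x) + matrix(rnorm(3600, 0, 0.02), 60, 60)
  expect_equal(pattern_match(w, x), 1)
  # anti-aligned weights give -1
  expect_equal(pattern_match(max(x) - x, x), -1)
  # independent weights: |P| below 3/N at N = 100, across seeds
  for (s in 1:5) {
    set.seed(s)
    x2 <- make_rates(n = 100, xi = 0)$x
    w2 <- matrix(runif(1e4), 100, 100)
    expect_lt(abs(pattern_match(w2, x2)), 3 / 100)
  }
  # invariance under jointly monotone affine rescaling of the weights
  set.seed(3)
  w3 <- matrix(runif(100), 10, 10)
  x3 <- matrix(runif(100), 10, 10)
  expect_equal(pattern_match(2.7 * w3 + 5, x3), pattern_match(w3, x3))
})

test_that("weights stay inside the unit interval during imprinting", {
  set.seed(4)
  res <- imprint_experiment("bimodal", xi = 0.4, duration_s = 2e4, dt_s = 10,
                            n = 40)
  expect_true(all(res$w >= 0 & res$w <= 1))
  expect_true(all(res$trajectory$match >= -1 & res$trajectory$match <= 1))
})

test_that("time_to_match reports the first crossing or Inf", {
  tr <- data.frame(time_s = c(10, 20, 30), match = c(0.2, 0.95, 0.9))
  expect_equal(time_to_match(tr), 20)
  expect_equal(time_to_match(tr, threshold = 0.99), Inf)
})
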