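test_that("synthetic expression profiles have the qualitative shapes", {
  prof <- synth_profiles()
  expect_gt(prof$doc2b[1], tail(prof$doc2b, 1))
  # the asynchronous sensor has a unique interior maximum
  k <- which.max(prof$doc2a)
  expect_gt(k, 1)
  expect_lt(k, nrow(prof))
  expect_true(all(diff(prof$doc2a[1:k]) > 0))
  expect_true(all(diff(prof$doc2a[k:nrow(prof)]) < 0))
  # the synchronous proxy rises monotonically
  expect_true(all(diff(prof$syt1 * prof$cplx1) >= 0))
  # deterministic without noise
  expect_identical(synth_profiles(), synth_profiles())
  expect_error(synth_profiles(ages = c(1, 1, 2)), "increasing")
})

test_that("expression tables round-trip and are validated", {
  prof <- synth_profiles(ages = 0:10)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(prof, path, row.names = FALSE)
  back <- read_expression_profile(path)
  expect_equal(back$doc2b, prof$doc2b)
  bad <- prof[, -2]
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_expression_profile(path), "doc2b")
})

test_that("release fractions follow normalized expression ratios", {
  # proxies in ratio 2:1:1 after per-gene normalization -> (0.5, 0.25, 0.25)
  prof <- data.frame(age = c(0, 1), doc2b = c(2, 1), doc2a = c(0.5, 1),
                     syt1 = c(1, 1), cplx1 = c(0.5, 1))
  class(prof) <- c("expression_profile", "data.frame")
  fr <- xi_from_expression(prof, 0)
  expect_equal(as.numeric(fr), c(0.5, 0.25, 0.25))
  # only the synchronous proxy expressed -> (0, 0, 1)
  prof2 <- data.frame(age = c(0, 1), doc2b = c(0, 1), doc2a = c(0, 1),
                      syt1 = c(5, 5), cplx1 = c(5, 5))
  class(prof2) <- c("expression_profile", "data.frame")
  expect_equal(as.numeric(xi_from_expression(prof2, 0)), c(0, 0, 1))
  # all proxies zero is undefined
  prof3 <- data.frame(age = c(0, 1), doc2b = c(0, 1), doc2a = c(0, 1),
                      syt1 = c(0, 1), cplx1 = c(1, 1))
  class(prof3) <- c("expression_profile", "data.frame")
  expect_error(xi_from_expression(prof3, 0), "undefined|zero")
  expect_error(xi_from_expression(prof, 99), "outside")
})

test_that("the default developmental schedule orders the modes correctly", {
  prof <- synth_profiles()
  ages <- seq(0, 20, by = 0.5)
  xi <- t(vapply(ages, function(a) as.numeric(xi_from_expression(prof, a)),
                 numeric(3)))
  expect_equal(rowSums(xi), rep(1, length(ages)), tolerance = 1e-12)
  # spontaneous dominates at the youngest age
  expect_gt(xi[1, 1], xi[1, 2])
  expect_gt(xi[1, 1], xi[1, 3])
  # synchronous share never decreases; spontaneous never increases after its peak
  expect_true(all(diff(xi[, 3]) >= -1e-9))
  pk <- which.max(xi[, 1])
  expect_true(all(diff(xi[pk:length(ages), 1]) <= 1e-9))
  # synchronous dominates at the oldest age
  expect_gt(xi[length(ages), 3], 0.9)
})

test_that("synaptogenesis adds binomially many synapses at the stage rate", {
  set.seed(10)
  conn <- matrix(0L, 200, 50)      # 10^4 open pairs
  w <- matrix(0, 200, 50)
  p <- 0.05
  out <- synaptogenesis_step(conn, w, w_bar0 = 20, k = p, dt_s = 1,
                             acceleration = 1)
  expected <- length(conn) * p
  expect_lt(abs(out$n_new - expected), 3 * sqrt(expected * (1 - p)))
  expect_equal(unique(out$w[out$conn == 1L]), 0.75 * 20)
  # saturated connectivity is a no-op
  full <- synaptogenesis_step(matrix(1L, 5, 5), matrix(1, 5, 5), 20,
                              k = 6.6e-8, dt_s = 1, acceleration = 1e6)
  expect_equal(full$n_new, 0L)
  # stage constants: accelerated early-development rate is 6.6e-2 per s
  st <- development_stage(1)
  expect_equal(st$k * 1e6, 6.6e-2, tolerance = 1e-12)
  expect_identical(development_stage(5)$label, "childhood")
  expect_identical(development_stage(15)$label, "adolescent_plus")
  expect_error(synaptogenesis_step(conn, w, 20, k = 1, dt_s = 10,
                                   acceleration = 1), "exceeds 1")
})

test_that("pruning removes strictly sub-threshold synapses and caps the rest", {
  conn <- matrix(1L, 1, 4)
  w <- matrix(c(0.69, 0.7, 1, 10) * 20, 1, 4)   # w_bar0 = 20
  out <- prune_step(conn, w, w_bar0 = 20)
  expect_equal(as.vector(out$conn), c(0L, 1L, 1L, 1L))
  expect_equal(out$w[1, 1], 0)
  expect_equal(out$w[1, 2], 0.7 * 20)            # exactly at threshold survives
  expect_equal(out$w[1, 4], 8 * 20)              # capped
  expect_equal(out$n_pruned, 1)
  none <- prune_step(conn, matrix(20, 1, 4), 20)
  expect_equal(none$n_pruned, 0)
})

test_that("divergence and learning rate recover a synthetic trajectory", {
  # construct snapshots whose high-group median grows linearly: D(t) slope
  # 0.01 per s, so the interior learning rate is 0.01 per s
  n_pre <- 10; n_post <- 2
  times <- seq(0, 100e3, by = 1000)
  high <- 1:3
  snaps <- sapply(times, function(t) {
    w <- matrix(1, n_pre, n_post)
    w[high, ] <- 1 + 0.01 * t / 1000
    as.vector(w)
  })
  lr <- learning_rate(snaps, times, high, n_pre, n_post)
  expect_equal(lr$divergence[1], 1)
  expect_equal(lr$learning_rate[-1], rep(0.01, length(times) - 1),
               tolerance = 1e-9)
  # equal groups: flat at one
  flat <- sapply(times, function(t) rep(2, n_pre * n_post))
  lrf <- learning_rate(flat, times, high, n_pre, n_post)
  expect_true(all(lrf$divergence == 1))
  expect_true(all(lrf$learning_rate[-1] == 0))
  expect_error(learning_rate(snaps, times, 1:10, n_pre, n_post), "non-empty")
})

test_that("density bookkeeping is exactly conservative", {
  set.seed(12)
  conn <- matrix(1L, 20, 5)
  masks <- list(conn)
  births <- deaths <- 0L
  for (k in 1:10) {
    kill <- which(conn == 1L)[runif(sum(conn)) < 0.1]
    conn[kill] <- 0L
    deaths <- deaths + length(kill)
    born <- which(conn == 0L)[runif(sum(conn == 0L)) < 0.2]
    conn[born] <- 1L
    births <- births + length(born)
    masks[[k + 1]] <- conn
  }
  d <- density_trajectory(masks)
  expect_equal(tail(d, 1), d[1] + births - deaths)
  # without pruning the trajectory is non-decreasing
  grow <- Reduce(function(m, k) {
    m[sample(which(m == 0L), 1)] <- 1L; m
  }, 1:5, accumulate = TRUE, init = matrix(0L, 3, 3))
  expect_true(all(diff(density_trajectory(grow)) >= 0))
})
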