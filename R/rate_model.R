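#' Exocytosis-rate matrix for the competitive rate model
#'
#' Builds the `n x n` matrix of per-synapse vesicle exocytosis rates as a
#' mixture of a spontaneous component (Gaussian across synapses, mean equal
#' to the grand mean of the evoked component, sd 0.05, truncated at zero) and
#' an evoked component that is bimodal by presynaptic row: a random subset of
#' rows fires "high" (0.8) and the rest "low" (0.4).
#'
#' @param n network side (presynaptic rows = postsynaptic columns).
#' @param xi spontaneous share of the mixture, in `[0, 1]`.
#' @param high_rate_frac fraction of high-rate presynaptic rows.
#' @param x_high,x_low evoked rates for the two groups.
#' @param sd_sve spread of the spontaneous component.
#' @param pattern optional integer vector of high rows (drawn at random when
#'   `NULL`).
#' @return List with the mixed matrix `x`, the pure evoked matrix `eve`, the
#'   spontaneous matrix `sve` and the `pattern` (high-row indices).
#' @export
make_rates <- function(n = 100, xi = 0, high_rate_frac = 0.2,
                       x_high = 0.8, x_low = 0.4, sd_sve = 0.05,
                       pattern = NULL) {
  if (xi < 0 || xi > 1) stop("xi must lie in [0, 1]", call. = FALSE)
  if (is.null(pattern)) pattern <- sample.int(n, round(high_rate_frac * n))
  eve <- matrix(x_low, n, n)
  eve[pattern, ] <- x_high
  sve <- matrix(pmax(rnorm(n * n, mean = mean(eve), sd = sd_sve), 0), n, n)
  list(x = xi * sve + (1 - xi) * eve, eve = eve, sve = sve, pattern = pattern)
}

#' One Euler step of the competitive rate model
#'
#' Weights evolve by column-wise competition around the mean exocytosis rate
#' onto each postsynaptic neuron: `dw = gamma * (x - xbar_j) * s * dt`, with
#' the soft-bound factor `s = w - w^2` on the potentiation side
#' (`x >= xbar_j`) and `s = w^2` on the depression side. Weights are clipped
#' to `[0, 1]` (the boundary values are fixed points of `s` in any case).
#' At the configured cadence, each column's total weight is renormalized to
#' its initial total — the rate-model analogue of homeostatic scaling.
#'
#' @param w weight matrix in `[0, 1]`.
#' @param x exocytosis-rate matrix (same shape).
#' @param dt_s step (s).
#' @param gamma rate constant (per s).
#' @param colsum_target per-column weight totals to renormalize to, or
#'   `NULL` to skip homeostatic normalization this step.
#' @param precomp precomputed [rate_drive()] for `x` (the rates are constant
#'   over a run, so the competition term need not be rebuilt every step).
#' @return Updated weight matrix.
#' @export
rate_step <- function(w, x, dt_s = 1, gamma = 1e-4, colsum_target = NULL,
                      precomp = NULL) {
  if (!all(dim(w) == dim(x))) stop("weight and rate matrices differ in shape",
                                   call. = FALSE)
  if (is.null(precomp)) precomp <- rate_drive(x, gamma)
  w2 <- w * w
  # s = w - w^2 on the potentiation side, w^2 on the depression side
  w <- w + (precomp$drive * dt_s) * (w2 + precomp$ltp * (w - 2 * w2))
  w[w < 0] <- 0
  w[w > 1] <- 1
  if (!is.null(colsum_target)) {
    cs <- colSums(w)
    fac <- ifelse(cs > 0, colsum_target / cs, 1)
    w <- sweep(w, 2, fac, `*`)
    w[w > 1] <- 1
  }
  w
}

#' @rdname rate_step
#' @return `rate_drive()`: list with the signed competition term `drive`
#'   (`gamma * (x - xbar_j)`) and the 0/1 potentiation-side mask `ltp`.
#' @export
rate_drive <- function(x, gamma = 1e-4) {
  xbar <- matrix(colMeans(x), nrow(x), ncol(x), byrow = TRUE)
  list(drive = gamma * (x - xbar), ltp = (x >= xbar) + 0)
}

#' Pattern-match statistic
#'
#' Mean sign-overlap between above-average weights and above-average
#' exocytosis rates: `P = mean((2 * [w >= wbar] - 1) * (2 * [x >= xbar] - 1))`
#' with both thresholds at the grand means. `P = 1` when weights align
#' perfectly with the rate pattern, `-1` for perfect anti-alignment, and
#' near 0 when they are unrelated (for large networks).
#'
#' @param w weight matrix.
#' @param x rate (pattern) matrix, same shape.
#' @return Scalar in `[-1, 1]`.
#' @export
pattern_match <- function(w, x) {
  if (!all(dim(w) == dim(x))) stop("weight and rate matrices differ in shape",
                                   call. = FALSE)
  sw <- 2 * (w >= mean(w)) - 1
  sx <- 2 * (x >= mean(x)) - 1
  mean(sw * sx)
}

#' Pattern-imprinting experiment
#'
#' Initializes an `n x n` weight matrix (unimodal Gaussian around the
#' bimodal mixture mean 0.5, or bimodal with the strong subset placed on a
#' random pattern distinct from the presented one), evolves it under
#' [rate_step()] with a presented rate pattern, and records the
#' pattern-match trajectory `P(t)` against the evoked (action-potential)
#' pattern.
#'
#' @param initial `"unimodal"` or `"bimodal"`.
#' @param xi spontaneous share of the exocytosis-rate mixture.
#' @param duration_s simulated seconds.
#' @param dt_s Euler step (s); the dynamics are orders of magnitude slower
#'   than even coarse steps.
#' @param n network side.
#' @param record_every_s sampling interval for `P(t)`.
#' @param homeo_every_s cadence of the column-normalization homeostasis.
#' @param gamma rate constant (per s).
#' @return List with data frame `trajectory` (`time_s`, `match`), the final
#'   weights `w`, the rate structure from [make_rates()].
#' @export
imprint_experiment <- function(initial = c("unimodal", "bimodal"), xi = 0,
                               duration_s = 2e5, dt_s = 10, n = 100,
                               record_every_s = 1000, homeo_every_s = 10,
                               gamma = 1e-4) {
  initial <- match.arg(initial)
  rates <- make_rates(n = n, xi = xi)
  n_high <- length(rates$pattern)
  w <- switch(initial,
    unimodal = matrix(rnorm(n * n, 0.5, 0.05), n, n),
    bimodal = {
      # previously encoded pattern, forced different from the presented one
      repeat {
        old <- sample.int(n, n_high)
        if (!setequal(old, rates$pattern)) break
      }
      m <- matrix(rnorm(n * n, 0.2, 0.02), n, n)
      m[old, ] <- rnorm(n_high * n, 0.8, 0.08)
      m
    })
  w[w < 0] <- 0; w[w > 1] <- 1
  colsum0 <- colSums(w)
  n_steps <- round(duration_s / dt_s)
  rec_stride <- max(1L, round(record_every_s / dt_s))
  homeo_stride <- max(1L, round(homeo_every_s / dt_s))
  pre <- rate_drive(rates$x, gamma)
  times <- numeric(); match <- numeric()
  for (s in seq_len(n_steps)) {
    target <- if (s %% homeo_stride == 0) colsum0 else NULL
    w <- rate_step(w, rates$x, dt_s = dt_s, gamma = gamma,
                   colsum_target = target, precomp = pre)
    if (s %% rec_stride == 0) {
      times <- c(times, s * dt_s)
      match <- c(match, pattern_match(w, rates$eve))
    }
  }
  list(trajectory = data.frame(time_s = times, match = match),
       w = w, rates = rates, initial = initial, xi = xi)
}

#' Time until the pattern match first reaches a threshold
#'
#' @param trajectory data frame `time_s`, `match` from
#'   [imprint_experiment()].
#' @param threshold match level (0.9).
#' @return First crossing time (s), or `Inf` if never reached.
#' @export
time_to_match <- function(trajectory, threshold = 0.9) {
  hit <- which(trajectory$match >= threshold)
  if (length(hit) == 0L) return(Inf)
  trajectory$time_s[hit[1L]]
}
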