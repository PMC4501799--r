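#' Divergence factor series
#'
#' Ratio of high-rate-group to low-rate-group median synaptic weight over
#' time, its finite-difference rate of change, and the maximal rate — the
#' summary used to compare how fast the three release modes drive synaptic
#' competition.
#'
#' @inheritParams learning_rate
#' @param smooth_s half-width (s) of a centred moving average applied to
#'   `D(t)` before differencing (0 = none); the rate of a noisy median ratio
#'   is otherwise dominated by snapshot noise.
#' @return List with data frame `series` (`time_s`, `divergence`, `rate`)
#'   and scalar `max_rate` (per s).
#' @export
divergence_series <- function(snapshots, times, high_group, n_pre, n_post,
                              smooth_s = 10) {
  lr <- learning_rate(snapshots, times, high_group, n_pre, n_post)
  D <- lr$divergence
  if (smooth_s > 0 && length(D) > 3) {
    stride <- if (length(lr$time_s) > 1) mean(diff(lr$time_s)) else 1
    k <- max(1L, round(smooth_s / stride))
    kern <- rep(1 / (2 * k + 1), 2 * k + 1)
    ok <- is.finite(D)
    Ds <- D
    Ds[ok] <- stats::filter(D[ok], kern, sides = 2)
    D <- Ds
  }
  rate <- c(NA_real_, diff(D) / diff(lr$time_s))
  list(series = data.frame(time_s = lr$time_s, divergence = D, rate = rate),
       max_rate = if (all(is.na(rate))) NA_real_ else max(rate, na.rm = TRUE))
}

#' Weight-distribution summary
#'
#' Density-normalized histogram plus spread statistics and a bimodality
#' diagnostic (two or more substantial modes of the smoothed density
#' separated by a dip).
#'
#' @param weights synaptic weights (finite; `NA` entries dropped).
#' @param bins histogram bin count.
#' @param min_peak_frac a mode counts as substantial when its density
#'   exceeds this fraction of the largest peak.
#' @param dip_frac a dip must fall below this fraction of the smaller of the
#'   two flanking peaks.
#' @return List `histogram` (data frame `mid`, `density`), `mean`, `sd`,
#'   `cv`, `bimodal`.
#' @export
weight_histogram <- function(weights, bins = 50, min_peak_frac = 0.1,
                             dip_frac = 0.8) {
  weights <- weights[is.finite(weights)]
  if (length(weights) == 0L) stop("no finite weights supplied", call. = FALSE)
  h <- graphics::hist(weights, breaks = bins, plot = FALSE)
  m <- mean(weights); s <- if (length(weights) > 1) sd(weights) else 0
  bimodal <- FALSE
  if (length(unique(weights)) > 1) {
    d <- density(weights)
    y <- d$y
    peaks <- which(diff(sign(diff(y))) == -2) + 1L
    peaks <- peaks[y[peaks] >= min_peak_frac * max(y[peaks])]
    if (length(peaks) >= 2) {
      for (k in seq_len(length(peaks) - 1L)) {
        seg <- y[peaks[k]:peaks[k + 1L]]
        if (min(seg) < dip_frac * min(y[peaks[k]], y[peaks[k + 1L]])) {
          bimodal <- TRUE
          break
        }
      }
    }
  } else {
    s <- 0
  }
  list(histogram = data.frame(mid = h$mids, density = h$density),
       mean = m, sd = s, cv = if (m > 0) s / m else NA_real_,
       bimodal = bimodal)
}

#' Coefficient of variation of weights per snapshot
#'
#' @param snapshots weight matrix `synapse x time`.
#' @return Numeric vector of CV values, one per snapshot column.
#' @export
weight_cv_series <- function(snapshots) {
  apply(snapshots, 2, function(wk) {
    wk <- wk[is.finite(wk)]
    sd(wk) / mean(wk)
  })
}
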