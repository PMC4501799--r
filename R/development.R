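#' Synthetic developmental expression profiles
#'
#' Parametric stand-in curves for the relative mRNA expression of the
#' calcium sensors that gate the three exocytosis modes across development:
#' Doc2b (spontaneous release; high early, decaying), Doc2a (asynchronous
#' evoked; a transient interior peak), and Synaptotagmin1 and Complexin1
#' (synchronous evoked; both rising monotonically, their product serving as
#' the synchronous proxy). These emulate the qualitative shapes of measured
#' human developmental transcriptome profiles, which are not bundled; a
#' measured table with the same columns can be supplied through
#' [read_expression_profile()].
#'
#' @param ages age grid (years, strictly increasing).
#' @param doc2b_mid,doc2b_slope centre (y) and width (y) of the Doc2b decay.
#' @param doc2a_peak,doc2a_width centre and width (y) of the Doc2a bump.
#' @param syt1_mid,syt1_slope,cplx1_mid,cplx1_slope sigmoid parameters (y)
#'   for the two synchronous-release genes.
#' @param noise_sd multiplicative log-normal noise sd (0 = deterministic).
#' @return Data frame of class `expression_profile` with columns `age`,
#'   `doc2b`, `doc2a`, `syt1`, `cplx1`.
#' @export
synth_profiles <- function(ages = seq(0, 20, by = 0.25),
                           doc2b_mid = 3, doc2b_slope = 1.5,
                           doc2a_peak = 4, doc2a_width = 2,
                           syt1_mid = 5, syt1_slope = 2,
                           cplx1_mid = 7, cplx1_slope = 2.5,
                           noise_sd = 0) {
  if (is.unsorted(ages, strictly = TRUE))
    stop("age grid must be strictly increasing", call. = FALSE)
  prof <- data.frame(
    age = ages,
    doc2b = 1 / (1 + exp((ages - doc2b_mid) / doc2b_slope)),
    doc2a = exp(-(ages - doc2a_peak)^2 / (2 * doc2a_width^2)),
    syt1 = 1 / (1 + exp(-(ages - syt1_mid) / syt1_slope)),
    cplx1 = 1 / (1 + exp(-(ages - cplx1_mid) / cplx1_slope)))
  if (noise_sd > 0)
    for (g in c("doc2b", "doc2a", "syt1", "cplx1"))
      prof[[g]] <- prof[[g]] * exp(rnorm(length(ages), 0, noise_sd))
  class(prof) <- c("expression_profile", "data.frame")
  prof
}

#' Read an expression-profile table
#'
#' Delimited text with header columns `age, doc2b, doc2a, syt1, cplx1`
#' (relative expression levels, non-negative, on a strictly increasing age
#' grid).
#'
#' @param path CSV/TSV file path.
#' @param sep field separator (guessed from the extension by default).
#' @return An `expression_profile` data frame.
#' @export
read_expression_profile <- function(path, sep = NULL) {
  if (is.null(sep))
    sep <- if (tolower(tools::file_ext(path)) %in% c("tsv", "tab")) "\t" else ","
  prof <- read.csv(path, sep = sep)
  need <- c("age", "doc2b", "doc2a", "syt1", "cplx1")
  miss <- setdiff(need, names(prof))
  if (length(miss))
    stop("expression table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  prof <- prof[, need]
  if (is.unsorted(prof$age, strictly = TRUE))
    stop("age grid must be strictly increasing", call. = FALSE)
  if (any(prof[, -1] < 0)) stop("expression levels must be non-negative",
                                call. = FALSE)
  class(prof) <- c("expression_profile", "data.frame")
  prof
}

#' Release fractions from expression levels
#'
#' Maps sensor expression at an age to release-mode fractions by forming the
#' ratio Doc2b : Doc2a : (Syt1 x Cplx1) after per-gene max-normalization over
#' the profile's age grid, then normalizing to sum one. Levels between grid
#' points are linearly interpolated.
#'
#' @param profile an `expression_profile`.
#' @param age age (years) within the grid.
#' @return A [release_fractions()] vector.
#' @export
xi_from_expression <- function(profile, age) {
  if (age < min(profile$age) || age > max(profile$age))
    stop("age outside the profile grid", call. = FALSE)
  lev <- vapply(c("doc2b", "doc2a", "syt1", "cplx1"), function(g) {
    y <- profile[[g]] / max(profile[[g]])
    stats::approx(profile$age, y, xout = age)$y
  }, numeric(1))
  seve_proxy <- lev[["syt1"]] * lev[["cplx1"]]
  tot <- lev[["doc2b"]] + lev[["doc2a"]] + seve_proxy
  if (tot <= 0)
    stop("all expression proxies are zero at this age; fractions undefined",
         call. = FALSE)
  release_fractions(xi_aeve = lev[["doc2a"]] / tot,
                    xi_seve = seve_proxy / tot)
}

#' Developmental stage lookup for synaptogenesis
#'
#' Stage-specific synapse-formation rate constants (per unconnected pair per
#' second, before acceleration): 6.6e-8 during early development, 5.0e-8
#' during early childhood, 2.5e-8 during adolescence and later.
#'
#' @param age age in years.
#' @param boundaries ages (years) ending the early and childhood stages.
#' @return List with `label` and rate constant `k` (per s).
#' @export
development_stage <- function(age, boundaries = c(2, 12)) {
  if (age < boundaries[1])
    list(label = "early", k = 6.6e-8)
  else if (age < boundaries[2])
    list(label = "childhood", k = 5.0e-8)
  else
    list(label = "adolescent_plus", k = 2.5e-8)
}

#' Synaptogenesis step
#'
#' Each unconnected presynaptic/postsynaptic pair independently forms a new
#' synapse with probability `k * acceleration * dt_s`; newly formed synapses
#' start at `init_frac * w_bar0` (above the pruning threshold, so newcomers
#' can be incorporated by ongoing plasticity) with a full vesicle pool.
#'
#' @param conn 0/1 connectivity matrix (`n_pre x n_post`).
#' @param w weight matrix, updated in place for newcomers.
#' @param w_bar0 mean equilibrated weight (pA).
#' @param k stage rate constant (per s per pair).
#' @param dt_s elapsed time this step (s).
#' @param acceleration rate speed-up factor (1e6 mirrors the compression of
#'   developmental time into simulated seconds).
#' @param init_frac newcomer weight as a fraction of `w_bar0`.
#' @return List with updated `conn`, `w` and integer `n_new`.
#' @export
synaptogenesis_step <- function(conn, w, w_bar0, k, dt_s, acceleration = 1e6,
                                init_frac = 0.75) {
  p <- k * acceleration * dt_s
  if (p > 1) stop("synaptogenesis probability exceeds 1; reduce dt", call. = FALSE)
  open <- which(conn == 0L)
  if (length(open) == 0L || p <= 0)
    return(list(conn = conn, w = w, n_new = 0L))
  born <- open[runif(length(open)) < p]
  conn[born] <- 1L
  w[born] <- init_frac * w_bar0
  list(conn = conn, w = w, n_new = length(born))
}

#' Activity-dependent pruning and capping
#'
#' Connected synapses weaker than `threshold_frac * w_bar0` are eliminated
#' (strict inequality: a synapse exactly at threshold survives); weights
#' above `cap_mult * w_bar0` are limited to the cap.
#'
#' @param conn 0/1 connectivity matrix.
#' @param w weight matrix.
#' @param w_bar0 mean equilibrated weight (pA).
#' @param threshold_frac pruning threshold fraction (0.7).
#' @param cap_mult upper-bound multiplier (8).
#' @return List with updated `conn`, `w`, and `n_pruned`.
#' @export
prune_step <- function(conn, w, w_bar0, threshold_frac = 0.7, cap_mult = 8) {
  if (w_bar0 <= 0) stop("w_bar0 must be positive", call. = FALSE)
  doomed <- conn == 1L & w < threshold_frac * w_bar0
  conn[doomed] <- 0L
  w[doomed] <- 0
  w[w > cap_mult * w_bar0] <- cap_mult * w_bar0
  list(conn = conn, w = w, n_pruned = sum(doomed))
}

#' Group-divergence and learning-rate series
#'
#' The divergence factor `D(t)` is the ratio of the median weight of
#' synapses from high-rate presynaptic neurons to that from low-rate
#' neurons; the learning rate is its finite-difference time derivative.
#'
#' @param snapshots weight matrix `synapse x time` (`NA` marks absent
#'   synapses; long-form column order is presynaptic-major as produced by
#'   [simulate_vtdp()]).
#' @param times snapshot times (ms).
#' @param high_group presynaptic indices of the high-rate group.
#' @param n_pre,n_post network dimensions.
#' @return Data frame `time_s`, `divergence` (`D`), `learning_rate`
#'   (`Lambda`, per s; `NA` at the first point and wherever the low-group
#'   median is zero).
#' @export
learning_rate <- function(snapshots, times, high_group, n_pre, n_post) {
  pre_of <- rep(seq_len(n_pre), n_post)
  is_high <- pre_of %in% high_group
  if (!any(is_high) || all(is_high))
    stop("both rate groups must be non-empty", call. = FALSE)
  D <- vapply(seq_along(times), function(k) {
    wk <- snapshots[, k]
    m_hi <- median(wk[is_high], na.rm = TRUE)
    m_lo <- median(wk[!is_high], na.rm = TRUE)
    if (!is.finite(m_lo) || m_lo == 0) return(NA_real_)
    m_hi / m_lo
  }, numeric(1))
  t_s <- times / 1000
  lam <- c(NA_real_, diff(D) / diff(t_s))
  data.frame(time_s = t_s, divergence = D, learning_rate = lam)
}

#' Synaptic density over time
#'
#' @param masks list of 0/1 connectivity matrices (time-ordered).
#' @return Integer vector of connected-pair counts.
#' @export
density_trajectory <- function(masks) {
  vapply(masks, function(m) sum(m == 1L), integer(1))
}

#' Developmental simulation
#'
#' Runs the full network across a developmental expression profile: the
#' release-mode fractions track the (interpolated) sensor expression ratios,
#' synaptogenesis adds synapses at the stage-specific rate, and weak
#' synapses are pruned. Developmental time is compressed: rates are
#' accelerated by `acceleration` so the whole profile spans
#' `total_years * 3.156e7 / acceleration` simulated seconds.
#'
#' @param net an equilibrated [network_init()] state (`w_bar0` set).
#' @param profile an `expression_profile`.
#' @param acceleration developmental-rate speed-up (1e6).
#' @param block_s simulated seconds between developmental updates
#'   (fractions, synaptogenesis, pruning).
#' @param snapshot_stride_ms stride of weight snapshots inside each block.
#' @param synaptogenesis,pruning logical switches.
#' @return List of class `vtdp_development`: `ages`, `xi` (fractions per
#'   block), `density`, `learning` (from [learning_rate()]), snapshot matrix
#'   and times, the final `net`.
#' @export
develop <- function(net, profile = synth_profiles(), acceleration = 1e6,
                    block_s = 1, snapshot_stride_ms = 1000,
                    synaptogenesis = TRUE, pruning = TRUE) {
  stopifnot(inherits(net, "vtdp_network"))
  if (is.na(net$w_bar0)) stop("equilibrate the network first", call. = FALSE)
  config <- net$config
  year_s <- 3.156e7
  total_years <- max(profile$age) - min(profile$age)
  duration_s <- total_years * year_s / acceleration
  n_blocks <- max(1L, round(duration_s / block_s))
  t_start <- net$t
  ages <- min(profile$age) + (seq_len(n_blocks) - 0.5) / n_blocks * total_years
  xi_hist <- matrix(NA_real_, n_blocks, 3,
                    dimnames = list(NULL, c("sve", "aeve", "seve")))
  density <- integer(n_blocks)
  snaps <- list(); snap_times <- list()
  for (b in seq_len(n_blocks)) {
    age <- ages[b]
    fr <- xi_from_expression(profile, age)
    xi_hist[b, ] <- as.numeric(fr)
    if (synaptogenesis) {
      st <- development_stage(age)
      sg <- synaptogenesis_step(net$conn, net$w, net$w_bar0, st$k, block_s,
                                acceleration = acceleration)
      if (sg$n_new > 0) {
        net$pa[sg$conn == 1L & net$conn == 0L] <- config$pool_total
        net$conn <- sg$conn
        net$w <- sg$w
      }
    }
    run <- simulate_vtdp(net, switch_schedule(0, fr), block_s * 1000,
                         snapshot_stride_ms = snapshot_stride_ms)
    net <- run$net
    if (length(run$snap_times)) {
      snaps[[length(snaps) + 1L]] <- run$snapshots
      snap_times[[length(snap_times) + 1L]] <- run$snap_times
    }
    if (pruning) {
      pr <- prune_step(net$conn, net$w, net$w_bar0,
                       threshold_frac = config$prune_frac,
                       cap_mult = config$weight_upper_mult)
      net$conn <- pr$conn
      net$w <- pr$w
    }
    density[b] <- sum(net$conn == 1L)
  }
  snapshots <- do.call(cbind, snaps)
  times <- unlist(snap_times)
  learning <- learning_rate(snapshots, times - t_start, net$high_group,
                            config$n_pre, config$n_post)
  structure(list(ages = ages, xi = xi_hist, density = density,
                 learning = learning, snapshots = snapshots,
                 snap_times = times, net = net,
                 block_s = block_s, acceleration = acceleration),
            class = "vtdp_development")
}
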