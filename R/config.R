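#' Simulation configuration with literature defaults
#'
#' Builds the full parameter set of the vesicle-timing dependent plasticity
#' (VTDP) model. Defaults are the published reference values for the
#' adaptive-threshold leaky integrate-and-fire neuron, the three-mode vesicle
#' release machinery, the pair-based plasticity rule and homeostatic scaling.
#' Times are in milliseconds internally except `tau_h` (seconds, the
#' homeostatic timescale); firing rates are in Hz at the interface; synaptic
#' weights are in units of peak EPSC current (pA), so the current term of the
#' membrane equation is in mV/ms.
#'
#' @param ... named overrides of any default field. Unknown names are an
#'   error.
#' @return A validated list of class `vtdp_config`.
#' @details Key fields: `v_rest` (-70.6 mV), `tau_mem` (9.4 ms), `c_mem`
#'   (281 pF), `theta_rest` (-50.4 mV), `theta_max` (30.4 mV), `tau_theta`
#'   (50 ms), `tau_ca` (100 ms), `tau_stdp` (20 ms), `tau_rec` (800 ms),
#'   `tau_h` (100 s), `gamma` (1e-4 per s, rate model), `n_pre` (500),
#'   `n_post` (10), `rate_low`/`rate_high` (4/8 Hz), `frac_high` (0.2),
#'   `n_ves_per_ap` (4), `pool_total` (100), `tau_alpha` (3 ms), `t_window`
#'   (20 ms), `lambda_ltp` (0.1), `mu` (0.4), `alpha_ltd` (0.11), `w0_frac`
#'   (0.05 of mean initial weight), `dt` (1 ms), `weight_upper_mult` (8),
#'   `prune_frac` (0.7), `seed`.
#' @examples
#' cfg <- vtdp_config()
#' cfg$tau_mem
#' mean_input_rate(cfg)  # 4.8 Hz at the default rate pattern
#' @export
vtdp_config <- function(...) {
  defaults <- list(
    v_rest = -70.6, tau_mem = 9.4, c_mem = 281,
    theta_rest = -50.4, theta_max = 30.4, tau_theta = 50,
    tau_ca = 100, tau_stdp = 20, tau_rec = 800,
    tau_h = 100,                 # seconds
    gamma = 1e-4,                # per second, competitive rate model
    n_pre = 500L, n_post = 10L,
    rate_low = 4, rate_high = 8, frac_high = 0.2,
    n_ves_per_ap = 4, pool_total = 100,
    tau_alpha = 3, t_window = 20,
    lambda_ltp = 0.1, mu = 0.4, alpha_ltd = 0.11,
    w0_frac = 0.05,
    dt = 1,
    seed = 1L,
    weight_upper_mult = 8,
    prune_frac = 0.7
  )
  over <- list(...)
  if (length(over) == 1L && is.null(names(over)) && is.list(over[[1L]]))
    over <- over[[1L]]
  if (length(over)) {
    if (is.null(names(over)) || any(!nzchar(names(over))))
      stop("all configuration overrides must be named", call. = FALSE)
    unknown <- setdiff(names(over), names(defaults))
    if (length(unknown))
      stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    defaults <- modifyList(defaults, over)
  }
  cfg <- structure(defaults, class = "vtdp_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  pos <- c("tau_mem", "c_mem", "tau_theta", "tau_ca", "tau_stdp", "tau_rec",
           "tau_h", "tau_alpha", "t_window", "dt", "gamma", "lambda_ltp",
           "alpha_ltd", "w0_frac", "weight_upper_mult", "pool_total")
  for (f in pos) {
    val <- cfg[[f]]
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val) || val <= 0)
      stop("configuration field '", f, "' must be a positive number",
           call. = FALSE)
  }
  if (cfg$frac_high < 0 || cfg$frac_high > 1)
    stop("configuration field 'frac_high' must lie in [0, 1]", call. = FALSE)
  if (cfg$mu <= 0 || cfg$mu >= 1)
    stop("configuration field 'mu' must lie in (0, 1)", call. = FALSE)
  if (cfg$pool_total < 1)
    stop("configuration field 'pool_total' must be >= 1", call. = FALSE)
  if (cfg$rate_low < 0 || cfg$rate_high < 0)
    stop("firing rates must be non-negative", call. = FALSE)
  if (cfg$n_pre < 1 || cfg$n_post < 1)
    stop("network sizes must be at least 1", call. = FALSE)
  for (r in c(cfg$rate_low, cfg$rate_high))
    if (r / 1000 * cfg$dt > 1)
      stop("rate * dt exceeds one spike per step; decrease dt", call. = FALSE)
  invisible(cfg)
}

#' @export
print.vtdp_config <- function(x, ...) {
  cat("VTDP simulation configuration\n")
  cat(sprintf("  network: %d presynaptic -> %d postsynaptic neurons\n",
              x$n_pre, x$n_post))
  cat(sprintf("  rates: %g%% at %g Hz, rest at %g Hz (mean %.3g Hz)\n",
              100 * x$frac_high, x$rate_high, x$rate_low, mean_input_rate(x)))
  cat(sprintf("  dt = %g ms, seed = %d\n", x$dt, as.integer(x$seed)))
  invisible(x)
}

#' Population mean input firing rate
#'
#' The nominal mean rate over the presynaptic population,
#' `frac_high * rate_high + (1 - frac_high) * rate_low`. This is the rate
#' that scales spontaneous release and the target of homeostatic scaling.
#'
#' @param config a [vtdp_config()] object.
#' @return Mean rate in Hz.
#' @export
mean_input_rate <- function(config) {
  config$frac_high * config$rate_high + (1 - config$frac_high) * config$rate_low
}

#' Read a configuration from a YAML or JSON file
#'
#' Unspecified fields take the package defaults; unknown keys are rejected
#' with an error naming the offending key.
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return A [vtdp_config()] object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  doc <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported configuration format '.", ext, "' (use YAML or JSON)",
         call. = FALSE))
  if (is.null(doc)) doc <- list()
  if (!is.list(doc)) stop("configuration file must contain a key-value mapping",
                          call. = FALSE)
  do.call(vtdp_config, doc)
}

#' Write a configuration to a YAML or JSON file
#'
#' Round-trips losslessly through [load_config()].
#'
#' @param config a [vtdp_config()] object.
#' @param path destination path (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "vtdp_config"))
  ext <- tolower(tools::file_ext(path))
  x <- unclass(config)
  switch(ext,
    yaml = , yml = yaml::write_yaml(x, path),
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA),
    stop("unsupported configuration format '.", ext, "'", call. = FALSE))
  invisible(path)
}

#' Release-mode fractions
#'
#' The per-synapse fractions of the vesicle machinery committed to
#' spontaneous (SVE), asynchronous evoked (aEVE) and synchronous evoked
#' (sEVE) exocytosis. The three fractions sum to one; the spontaneous share
#' is the complement of the two evoked shares, which is how the developmental
#' switch from spontaneous to evoked release is expressed.
#'
#' @param xi_aeve asynchronous evoked fraction, in `[0, 1]`.
#' @param xi_seve synchronous evoked fraction, in `[0, 1]`.
#' @return Named numeric vector `c(sve, aeve, seve)` of class
#'   `vtdp_fractions`.
#' @examples
#' release_fractions(0, 0)      # pure spontaneous release
#' release_fractions(0.3, 0.3)  # mixed; spontaneous share 0.4
#' @export
release_fractions <- function(xi_aeve = 0, xi_seve = 0) {
  if (!is.numeric(xi_aeve) || !is.numeric(xi_seve) ||
      length(xi_aeve) != 1L || length(xi_seve) != 1L)
    stop("fractions must be numeric scalars", call. = FALSE)
  if (xi_aeve < 0 || xi_seve < 0)
    stop("release fractions must be non-negative", call. = FALSE)
  if (xi_aeve + xi_seve > 1 + 1e-12)
    stop("evoked fractions sum to more than one", call. = FALSE)
  out <- c(sve = 1 - xi_aeve - xi_seve, aeve = xi_aeve, seve = xi_seve)
  out[out < 0] <- 0
  structure(out, class = "vtdp_fractions")
}

#' Derive independent named random substreams from one master seed
#'
#' One master seed deterministically spawns named integer seeds (below 2^31)
#' for each stochastic component, so adding a diagnostic that consumes
#' randomness in one component never perturbs the others.
#'
#' @param seed master integer seed.
#' @param names character vector of substream names.
#' @return Named integer vector of seeds.
#' @export
vtdp_streams <- function(seed,
                         names = c("spikes", "release", "weights",
                                   "rate_model", "development", "protocol")) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  setNames(sample.int(.Machine$integer.max - 1L, length(names)), names)
}
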