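#' Event logs
#'
#' Timestamped streams produced by a simulation: presynaptic spikes, vesicle
#' releases (tagged with their exocytosis mode) and postsynaptic spikes.
#' Internally an event log is a data frame with columns `time_ms`, `stream`
#' (`"pre_spike"`, `"release"`, `"post_spike"`), `pre_idx`, `post_idx` and
#' `mode` (`"SVE"`, `"aEVE"`, `"sEVE"`, or `NA` for spike streams).
#'
#' @name event_log
NULL

MODE_LEVELS <- c("SVE", "aEVE", "sEVE")

#' @rdname event_log
#' @return `empty_event_log()`: a zero-row event-log data frame.
#' @export
empty_event_log <- function() {
  data.frame(time_ms = numeric(), stream = character(),
             pre_idx = integer(), post_idx = integer(),
             mode = character(), stringsAsFactors = FALSE)
}

# assemble an event log from the raw vectors the simulation core returns
build_event_log <- function(pre_spikes, events, post_t, post_j) {
  n_rel <- length(events$t)
  rel <- data.frame(time_ms = as.numeric(events$t),
                    stream = rep("release", n_rel),
                    pre_idx = as.integer(events$i),
                    post_idx = as.integer(events$j),
                    mode = MODE_LEVELS[as.integer(events$mode)],
                    stringsAsFactors = FALSE)
  # releases of k vesicles in one step appear as k rows
  if (n_rel && any(events$count > 1L))
    rel <- rel[rep(seq_len(nrow(rel)), as.integer(events$count)), , drop = FALSE]
  n_pre <- length(pre_spikes$t)
  pre <- data.frame(time_ms = as.numeric(pre_spikes$t),
                    stream = rep("pre_spike", n_pre),
                    pre_idx = as.integer(pre_spikes$i),
                    post_idx = rep(NA_integer_, n_pre),
                    mode = rep(NA_character_, n_pre), stringsAsFactors = FALSE)
  n_post <- length(post_t)
  post <- data.frame(time_ms = as.numeric(post_t),
                     stream = rep("post_spike", n_post),
                     pre_idx = rep(NA_integer_, n_post),
                     post_idx = as.integer(post_j),
                     mode = rep(NA_character_, n_post), stringsAsFactors = FALSE)
  out <- rbind(pre, rel, post)
  out <- out[order(out$time_ms, match(out$stream, c("pre_spike", "release", "post_spike"))), ]
  rownames(out) <- NULL
  validate_event_log(out)
  out
}

validate_event_log <- function(log) {
  stopifnot(all(c("time_ms", "stream", "pre_idx", "post_idx", "mode") %in% names(log)))
  for (s in unique(log$stream)) {
    tt <- log$time_ms[log$stream == s]
    if (is.unsorted(tt)) stop("event times within stream '", s,
                              "' are not non-decreasing", call. = FALSE)
  }
  bad <- !is.na(log$mode) & !(log$mode %in% MODE_LEVELS)
  if (any(bad)) stop("unknown release mode tag in event log", call. = FALSE)
  invisible(log)
}

#' @rdname event_log
#' @param log an event-log data frame.
#' @param path CSV file path.
#' @export
write_event_log <- function(log, path) {
  validate_event_log(log)
  write.csv(log, path, row.names = FALSE)
  invisible(path)
}

#' @rdname event_log
#' @export
read_event_log <- function(path) {
  log <- read.csv(path, stringsAsFactors = FALSE)
  log$mode <- as.character(log$mode)
  validate_event_log(log)
  log
}
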