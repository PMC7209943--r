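# Nasal-airflow traces: container, synthetic generator, CSV I/O.
#
# The generator models respiration as one half-wave rectified sinusoid per
# breath: inspiration is the positive half-period (positive flow =
# inhalation by convention), expiration is flat zero.  Only the integrated
# inspiratory volume matters to the sniff criterion, so breath-shape
# realism beyond the volume is not modelled.

#' Airflow trace container
#'
#' A uniformly sampled nasal-flow series (ml/s) with an optional set of
#' labelled epoch annotations.  Epochs mark hand-at-face intervals in the
#' study's coding convention: hand contact below the eyebrows and above
#' the lower lip; the annotations are taken as given (no video
#' processing).
#'
#' @param flow numeric vector of flow samples in ml/s (positive =
#'   inhalation; use `invert_flow()` for the opposite convention).
#' @param fs sampling rate in Hz.
#' @param epochs optional data.frame with columns `start_s`, `end_s`,
#'   `label`; intervals must lie within the trace and must not overlap
#'   within a label.
#' @return an `airflow_trace`.
#' @export
airflow_trace <- function(flow, fs, epochs = NULL) {
  stopifnot(is.numeric(flow), length(flow) >= 2)
  if (!is.numeric(fs) || fs <= 0) stop("fs must be > 0")
  if (any(!is.finite(flow))) stop("flow samples must be finite")
  duration <- length(flow) / fs
  if (!is.null(epochs)) {
    stopifnot(is.data.frame(epochs),
              all(c("start_s", "end_s", "label") %in% names(epochs)))
    if (any(epochs$start_s < 0) || any(epochs$end_s > duration + 1e-9) ||
        any(epochs$end_s <= epochs$start_s)) {
      stop("epochs must be proper intervals within the trace")
    }
    for (lab in unique(epochs$label)) {
      e <- epochs[epochs$label == lab, ]
      e <- e[order(e$start_s), ]
      if (nrow(e) > 1 && any(e$start_s[-1] < e$end_s[-nrow(e)] - 1e-9)) {
        stop(sprintf("epochs with label '%s' overlap", lab))
      }
    }
  }
  structure(list(flow = as.numeric(flow), fs = fs, duration = duration,
                 epochs = epochs),
            class = "airflow_trace")
}

#' @export
print.airflow_trace <- function(x, ...) {
  cat(sprintf("Airflow trace: %.1f s at %g Hz (%d samples)\n",
              x$duration, x$fs, length(x$flow)))
  if (!is.null(x$epochs)) {
    cat(sprintf("  epochs: %d (%s)\n", nrow(x$epochs),
                paste(unique(x$epochs$label), collapse = ", ")))
  }
  invisible(x)
}

#' @rdname airflow_trace
#' @param trace an `airflow_trace` recorded with negative-inhalation
#'   convention.
#' @export
invert_flow <- function(trace) {
  stopifnot(inherits(trace, "airflow_trace"))
  airflow_trace(-trace$flow, trace$fs, trace$epochs)
}

#' Trace simulation configuration
#'
#' @param duration_s trace length in seconds.
#' @param fs sampling rate in Hz (default 25, typical for nasal-cannula
#'   recordings).
#' @param baseline_amplitude peak inspiratory flow of an ordinary breath,
#'   ml/s.
#' @param breath_period_s duration of a full breath cycle, seconds
#'   (inspiration occupies the first half).
#' @param noise_sd additive Gaussian noise s.d., ml/s.
#' @param events data.frame with columns `onset_s` and
#'   `relative_volume_change`: each event scales the inspiratory volume of
#'   the breath containing its onset by `1 + relative_volume_change`.
#'   Events must be at least one breath period apart.
#' @param seed integer seed.
#' @return a validated `trace_sim_config` list.
#' @export
trace_sim_config <- function(duration_s = 120, fs = 25,
                             baseline_amplitude = 100, breath_period_s = 4,
                             noise_sd = 0, events = NULL, seed = NULL) {
  if (duration_s <= 0) stop("duration_s must be > 0")
  if (fs <= 0) stop("fs must be > 0")
  if (breath_period_s <= 0 || baseline_amplitude <= 0) {
    stop("breath_period_s and baseline_amplitude must be > 0")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.null(events)) {
    stopifnot(is.data.frame(events),
              all(c("onset_s", "relative_volume_change") %in% names(events)))
    if (any(events$onset_s < 0 | events$onset_s >= duration_s)) {
      stop("event onsets must lie within [0, duration_s)")
    }
    on <- sort(events$onset_s)
    if (length(on) > 1 && any(diff(on) < breath_period_s)) {
      stop("events must be at least one breath period apart")
    }
  }
  structure(list(duration_s = duration_s, fs = fs,
                 baseline_amplitude = baseline_amplitude,
                 breath_period_s = breath_period_s, noise_sd = noise_sd,
                 events = events, seed = seed),
            class = "trace_sim_config")
}

#' Simulate a nasal-airflow trace
#'
#' Generates a quasi-periodic respiration trace: one half-wave rectified
#' sinusoidal inspiration per breath period, flat expiration, plus
#' additive Gaussian noise.  Each requested event is realized by scaling
#' the amplitude (hence the integrated inspiratory volume) of the breath
#' containing its onset by `1 + relative_volume_change`.
#'
#' @param config a [trace_sim_config()].
#' @return a list with `trace` (an [airflow_trace()]) and `events` (the
#'   ground-truth data.frame: `breath_index`, `onset_s`,
#'   `relative_volume_change`).
#' @examples
#' sim <- simulate_airflow(trace_sim_config(duration_s = 20, seed = 1))
#' sim$trace
#' @export
simulate_airflow <- function(config) {
  stopifnot(inherits(config, "trace_sim_config"))
  n <- floor(config$duration_s * config$fs)
  t <- (seq_len(n) - 1) / config$fs
  period <- config$breath_period_s
  breath_idx <- floor(t / period)          # 0-based breath index per sample
  phase <- t - breath_idx * period

  amp <- rep(config$baseline_amplitude, max(breath_idx) + 1)
  truth <- data.frame(breath_index = integer(0), onset_s = numeric(0),
                      relative_volume_change = numeric(0))
  if (!is.null(config$events) && nrow(config$events)) {
    ev_breath <- floor(config$events$onset_s / period)
    amp[ev_breath + 1] <- config$baseline_amplitude *
      (1 + config$events$relative_volume_change)
    truth <- data.frame(breath_index = ev_breath + 1L,
                        onset_s = ev_breath * period,
                        relative_volume_change =
                          config$events$relative_volume_change)
    truth <- truth[order(truth$onset_s), ]
    rownames(truth) <- NULL
  }

  flow <- amp[breath_idx + 1] * pmax(sin(2 * pi * phase / period), 0)
  if (config$noise_sd > 0) {
    flow <- flow + with_seed(config$seed,
                             stats::rnorm(n, sd = config$noise_sd))
  }
  list(trace = airflow_trace(flow, config$fs), events = truth)
}

#' Simulate an epoch-annotated trace
#'
#' Builds a respiration trace whose flow is multiplied by `hand_gain`
#' inside the given hand-at-face intervals; the complement of those
#' intervals is labelled as baseline.  Used to exercise
#' [epoch_flow_comparison()] with a known flow ratio.
#'
#' @param config a [trace_sim_config()] (its `events` are ignored here).
#' @param hand_epochs data.frame with `start_s`, `end_s` hand-at-face
#'   intervals.
#' @param hand_gain multiplicative flow change during hand epochs.
#' @return an [airflow_trace()] with `hand` and `baseline` epochs.
#' @export
simulate_epoch_trace <- function(config, hand_epochs, hand_gain = 2) {
  stopifnot(inherits(config, "trace_sim_config"),
            is.data.frame(hand_epochs),
            all(c("start_s", "end_s") %in% names(hand_epochs)))
  sim <- simulate_airflow(config)
  flow <- sim$trace$flow
  fs <- config$fs
  t <- (seq_along(flow) - 1) / fs
  in_hand <- rep(FALSE, length(flow))
  for (i in seq_len(nrow(hand_epochs))) {
    in_hand <- in_hand |
      (t >= hand_epochs$start_s[i] & t < hand_epochs$end_s[i])
  }
  flow[in_hand] <- flow[in_hand] * hand_gain

  hand <- data.frame(start_s = hand_epochs$start_s,
                     end_s = hand_epochs$end_s, label = "hand")
  base <- complement_intervals(hand_epochs, config$duration_s)
  base$label <- "baseline"
  airflow_trace(flow, fs, rbind(hand, base))
}

# Complement of a set of intervals within [0, duration].
complement_intervals <- function(iv, duration) {
  iv <- iv[order(iv$start_s), , drop = FALSE]
  starts <- c(0, iv$end_s)
  ends <- c(iv$start_s, duration)
  keep <- ends - starts > 1e-9
  data.frame(start_s = starts[keep], end_s = ends[keep])
}

#' Read and write airflow traces as CSV
#'
#' Traces are stored as two-column CSV (`time_s`, `flow_ml_s`); the
#' sampling rate is recovered from the median time step.  Epochs travel in
#' a JSON sidecar (see [read_epochs()]).
#'
#' @param path CSV path.
#' @param epochs optional epochs data.frame to attach after reading.
#' @return `read_trace()` returns an [airflow_trace()].
#' @export
read_trace <- function(path, epochs = NULL) {
  if (!file.exists(path)) stop_data(sprintf("no such file: %s", path))
  df <- utils::read.csv(path)
  if (!all(c("time_s", "flow_ml_s") %in% names(df))) {
    stop_data("trace CSV must have columns time_s, flow_ml_s")
  }
  if (nrow(df) < 2) stop_data("trace must have at least 2 samples")
  fs <- 1 / stats::median(diff(df$time_s))
  airflow_trace(df$flow_ml_s, fs, epochs)
}

#' @rdname read_trace
#' @param trace an [airflow_trace()].
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "airflow_trace"))
  t <- (seq_along(trace$flow) - 1) / trace$fs
  utils::write.csv(data.frame(time_s = t, flow_ml_s = trace$flow), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname read_trace
#' @export
read_epochs <- function(path) {
  if (!file.exists(path)) stop_data(sprintf("no such file: %s", path))
  df <- as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  if (!all(c("start_s", "end_s", "label") %in% names(df))) {
    stop_data("epochs JSON must have fields start_s, end_s, label")
  }
  df
}
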