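# Breath segmentation and the sniff criterion.
#
# A sniff is a breath whose normalized inspiratory volume (volume divided
# by the mean breath volume of a baseline respiration window) deviates by
# more than 15% from 1 in either direction, and/or whose inclusion shifts
# the standard deviation of normalized volume over ongoing respiration
# above 0.35.

#' Segment a trace into breaths
#'
#' Delimits inspirations as contiguous runs where the smoothed flow
#' exceeds a threshold, and integrates the raw flow over each run
#' (trapezoidal rule) to obtain inspiratory volumes.  Detection uses
#' hysteresis: onsets and offsets are placed at the low `threshold`, but a
#' run only counts as a breath if its smoothed peak also clears
#' `peak_threshold`, so noise excursions during expiration are not called
#' breaths.  Runs shorter than `min_duration_s` are dropped and
#' sub-threshold gaps shorter than `min_gap_s` are closed.  A flat trace
#' yields an empty table with a warning.
#'
#' @param trace an [airflow_trace()] (positive flow = inhalation; see
#'   [invert_flow()]).
#' @param smooth_window_s width of the centered moving-average smoother,
#'   seconds.
#' @param threshold flow threshold in ml/s delimiting inspiration;
#'   defaults to 5% of the 95th percentile of the smoothed flow.
#' @param peak_threshold minimum smoothed peak flow for a run to count as
#'   a breath; defaults to five times `threshold` (25% of the 95th
#'   percentile under the default threshold).
#' @param min_duration_s minimum inspiration duration, seconds.
#' @param min_gap_s above-threshold runs separated by a sub-threshold gap
#'   shorter than this are merged into one breath; a noise dip inside an
#'   inspiration must not split it in two.
#' @return a data.frame of class `breath_table`: `breath`, `onset`,
#'   `offset` (sample indices), `t_onset`, `t_offset` (seconds), `volume`
#'   (ml), `peak_flow` (ml/s).
#' @export
segment_breaths <- function(trace, smooth_window_s = 0.2, threshold = NULL,
                            min_duration_s = 0.2, min_gap_s = 0.5,
                            peak_threshold = NULL) {
  stopifnot(inherits(trace, "airflow_trace"))
  flow <- trace$flow
  fs <- trace$fs
  w <- max(1L, round(smooth_window_s * fs))
  if (w %% 2 == 0) w <- w + 1L
  h <- (w - 1L) %/% 2L
  padded <- c(rep(0, h), flow, rep(0, h))   # zero flow = flat expiration
  sm <- as.numeric(stats::filter(padded, rep(1 / w, w), sides = 2))
  sm <- sm[h + seq_along(flow)]
  sm[is.na(sm)] <- 0

  if (is.null(threshold)) {
    threshold <- 0.05 * stats::quantile(sm, 0.95, names = FALSE)
  }
  if (is.null(peak_threshold)) peak_threshold <- 5 * threshold
  if (max(sm) <= max(threshold, 0)) {
    warning("flat trace: no breaths found", call. = FALSE)
    return(empty_breath_table())
  }

  above <- sm > threshold
  # close sub-threshold gaps shorter than min_gap_s so a noise dip cannot
  # split one inspiration into two breaths
  gaps <- rle(above)
  gap_ends <- cumsum(gaps$lengths)
  gap_starts <- gap_ends - gaps$lengths + 1
  close <- !gaps$values & (gaps$lengths / fs) < min_gap_s
  close[c(1, length(close))] <- FALSE     # never close edge gaps
  for (g in which(close)) above[gap_starts[g]:gap_ends[g]] <- TRUE

  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  sm_peak <- mapply(function(i, j) max(sm[i:j]), starts, ends)
  keep <- runs$values &
    (runs$lengths / fs) >= min_duration_s &
    sm_peak > peak_threshold
  if (!any(keep)) {
    warning("no breaths longer than min_duration_s", call. = FALSE)
    return(empty_breath_table())
  }
  onset <- starts[keep]
  offset <- ends[keep]
  t <- (seq_along(flow) - 1) / fs
  vols <- mapply(function(i, j) {
    max(pracma::trapz(t[i:j], flow[i:j]), 0)
  }, onset, offset)
  peaks <- mapply(function(i, j) max(flow[i:j]), onset, offset)
  structure(data.frame(breath = seq_along(onset), onset = onset,
                       offset = offset, t_onset = t[onset],
                       t_offset = t[offset], volume = vols,
                       peak_flow = peaks),
            class = c("breath_table", "data.frame"))
}

empty_breath_table <- function() {
  structure(data.frame(breath = integer(0), onset = integer(0),
                       offset = integer(0), t_onset = numeric(0),
                       t_offset = numeric(0), volume = numeric(0),
                       peak_flow = numeric(0)),
            class = c("breath_table", "data.frame"))
}

#' Detect sniff events
#'
#' Applies the two-branch sniff criterion to every breath outside the
#' baseline window:
#'
#' * **volume branch** — the breath's normalized volume
#'   `v = volume / mean(baseline volumes)` deviates from 1 by more than
#'   `thresholds$vol` (default 0.15) in either direction;
#' * **s.d. branch** — the breath shifts the s.d. of normalized volume
#'   over ongoing respiration above `thresholds$sd` (default 0.35): with
#'   `sd_method = "rolling"` (default) the branch fires when the rolling
#'   s.d. of normalized volume over the trailing `sd_window` breaths
#'   exceeds the threshold with the breath included but not without it.
#'   `sd_method = "zscore"` instead fires when
#'   `(volume - baseline mean) / baseline s.d. > thresholds$sd`; it is
#'   disabled with a warning when the baseline volumes have (near) zero
#'   variance.
#'
#' The baseline window is held out: baseline breaths are never flagged.
#'
#' @param trace an [airflow_trace()].
#' @param baseline_window numeric `c(start_s, end_s)` delimiting baseline
#'   respiration.  Default: intervals labelled `"baseline"` in the trace
#'   epochs if present, otherwise the first 60 s.
#' @param thresholds list with elements `vol` (fractional volume change)
#'   and `sd` (s.d. shift).
#' @param sd_method `"rolling"` (default) or `"zscore"`, see above.
#' @param sd_window breaths in the rolling s.d. window.
#' @param breaths optional pre-computed [segment_breaths()] result.
#' @return a data.frame of class `sniff_events`: `breath`, `t_onset`,
#'   `volume`, `normalized_volume`, `norm_change` (signed fraction),
#'   `sd_shift` (baseline s.d. units), `branch`
#'   (`"volume"`/`"sd"`/`"both"`), `direction`
#'   (`"increase"`/`"decrease"`).
#' @export
detect_sniffs <- function(trace, baseline_window = NULL,
                          thresholds = list(vol = 0.15, sd = 0.35),
                          sd_method = c("rolling", "zscore"),
                          sd_window = 10, breaths = NULL) {
  stopifnot(inherits(trace, "airflow_trace"))
  sd_method <- match.arg(sd_method)
  if (is.null(breaths)) breaths <- segment_breaths(trace)
  if (nrow(breaths) == 0) return(empty_sniff_events())

  base_iv <- baseline_intervals(trace, baseline_window)
  in_base <- vapply(seq_len(nrow(breaths)), function(i) {
    any(breaths$t_onset[i] >= base_iv$start_s &
          breaths$t_offset[i] <= base_iv$end_s)
  }, logical(1))
  if (sum(in_base) < 3) {
    stop("baseline window must contain at least 3 breaths")
  }

  mean_base <- mean(breaths$volume[in_base])
  sd_base <- stats::sd(breaths$volume[in_base])
  nv <- breaths$volume / mean_base
  sd_shift <- if (sd_base > 1e-12 * mean_base) {
    (breaths$volume - mean_base) / sd_base
  } else rep(NA_real_, nrow(breaths))

  vol_hit <- abs(nv - 1) > thresholds$vol

  sd_hit <- rep(FALSE, nrow(breaths))
  if (sd_method == "zscore") {
    if (all(is.na(sd_shift))) {
      warning("baseline volumes have zero variance; s.d. branch disabled",
              call. = FALSE)
    } else {
      sd_hit <- sd_shift > thresholds$sd
    }
  } else {
    for (i in which(!in_base)) {
      lo <- max(1, i - sd_window + 1)
      win <- nv[lo:i]
      if (length(win) >= 3) {
        s_with <- stats::sd(win)
        s_without <- stats::sd(nv[lo:(i - 1)])
        sd_hit[i] <- s_with > thresholds$sd &&
          (is.na(s_without) || s_without <= thresholds$sd)
      }
    }
  }

  hit <- (vol_hit | sd_hit) & !in_base
  if (!any(hit)) return(empty_sniff_events())
  idx <- which(hit)
  branch <- ifelse(vol_hit[idx] & sd_hit[idx], "both",
                   ifelse(vol_hit[idx], "volume", "sd"))
  structure(data.frame(
    breath = breaths$breath[idx],
    t_onset = breaths$t_onset[idx],
    volume = breaths$volume[idx],
    normalized_volume = nv[idx],
    norm_change = nv[idx] - 1,
    sd_shift = sd_shift[idx],
    branch = branch,
    direction = ifelse(nv[idx] >= 1, "increase", "decrease")
  ), class = c("sniff_events", "data.frame"))
}

empty_sniff_events <- function() {
  structure(data.frame(breath = integer(0), t_onset = numeric(0),
                       volume = numeric(0), normalized_volume = numeric(0),
                       norm_change = numeric(0), sd_shift = numeric(0),
                       branch = character(0), direction = character(0)),
            class = c("sniff_events", "data.frame"))
}

baseline_intervals <- function(trace, baseline_window) {
  if (!is.null(baseline_window)) {
    return(data.frame(start_s = baseline_window[1],
                      end_s = baseline_window[2]))
  }
  if (!is.null(trace$epochs) && any(trace$epochs$label == "baseline")) {
    e <- trace$epochs[trace$epochs$label == "baseline", ]
    return(data.frame(start_s = e$start_s, end_s = e$end_s))
  }
  data.frame(start_s = 0, end_s = min(60, trace$duration))
}

#' Epoch-conditioned flow comparison across subjects
#'
#' For each subject's trace, computes the mean flow over samples inside
#' each epoch label (hand-at-face vs baseline), then compares the two
#' conditions across subjects: condition means and s.d.s, paired mean
#' difference, paired t statistic with `n - 1` degrees of freedom, the
#' count of subjects whose flow increased, and the exact
#' [binomial_direction_test()] on that count.  Subjects missing either
#' label are excluded with a message.  The summary is invariant to the
#' order of epochs within a trace and to the order of subjects.
#'
#' @param subjects a list of [airflow_trace()] objects with epochs, or a
#'   single trace.
#' @param labels character `c(baseline, hand)` epoch labels to compare.
#' @return an object of class `epoch_comparison`: list with `per_subject`
#'   (data.frame of per-condition mean flows), `n`, `mean_baseline`,
#'   `sd_baseline`, `mean_hand`, `sd_hand`, `mean_diff`, `t`, `df`,
#'   `p_t` (paired two-sided), `n_increase`, `p_binomial`.
#' @export
epoch_flow_comparison <- function(subjects, labels = c("baseline", "hand")) {
  if (inherits(subjects, "airflow_trace")) subjects <- list(subjects)
  stopifnot(length(labels) == 2)
  rows <- list()
  for (i in seq_along(subjects)) {
    tr <- subjects[[i]]
    stopifnot(inherits(tr, "airflow_trace"))
    if (is.null(tr$epochs) || !all(labels %in% tr$epochs$label)) {
      message(sprintf("subject %d lacks both epoch labels; excluded", i))
      next
    }
    m <- vapply(labels, function(lab) {
      e <- tr$epochs[tr$epochs$label == lab, , drop = FALSE]
      t <- (seq_along(tr$flow) - 1) / tr$fs
      sel <- rep(FALSE, length(t))
      for (j in seq_len(nrow(e))) {
        sel <- sel | (t >= e$start_s[j] & t < e$end_s[j])
      }
      mean(tr$flow[sel])
    }, numeric(1))
    rows[[length(rows) + 1]] <- data.frame(subject = i,
                                           mean_baseline = m[1],
                                           mean_hand = m[2])
  }
  if (!length(rows)) stop("no subject carries both epoch labels")
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  d <- per$mean_hand - per$mean_baseline
  n <- nrow(per)

  scale <- max(1, mean(abs(per$mean_baseline)))
  if (n >= 2 && stats::sd(d) > 1e-10 * scale) {
    tt <- stats::t.test(per$mean_hand, per$mean_baseline, paired = TRUE)
    t_stat <- unname(tt$statistic); p_t <- tt$p.value
  } else if (abs(mean(d)) <= 1e-10 * scale) {
    t_stat <- 0; p_t <- 1
  } else {
    t_stat <- sign(mean(d)) * Inf; p_t <- NA_real_
  }
  n_inc <- sum(d > 0)
  structure(list(per_subject = per, n = n,
                 mean_baseline = mean(per$mean_baseline),
                 sd_baseline = stats::sd(per$mean_baseline),
                 mean_hand = mean(per$mean_hand),
                 sd_hand = stats::sd(per$mean_hand),
                 mean_diff = mean(d), t = t_stat, df = n - 1, p_t = p_t,
                 n_increase = n_inc,
                 p_binomial = binomial_direction_test(n_inc, n)),
            class = "epoch_comparison")
}

#' @export
print.epoch_comparison <- function(x, ...) {
  cat(sprintf("Epoch flow comparison over %d subjects\n", x$n))
  cat(sprintf("  baseline flow = %.2f +/- %.2f ml/s\n",
              x$mean_baseline, x$sd_baseline))
  cat(sprintf("  hand-at-face flow = %.2f +/- %.2f ml/s\n",
              x$mean_hand, x$sd_hand))
  cat(sprintf("  paired t(%d) = %.3f, p = %.4g\n", x$df, x$t, x$p_t))
  cat(sprintf("  %d of %d subjects increased (binomial p = %.4g)\n",
              x$n_increase, x$n, x$p_binomial))
  invisible(x)
}
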