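#' Sharp-wave ripple detection parameters
#'
#' Defaults follow the standard slice SWR workflow: sharp waves are local
#' maxima of the 45 Hz low-passed, mean-subtracted trace exceeding 2.5 x its
#' SD, with a minimum inter-event interval of 80 ms; the event window is
#' 125 ms centered on the sharp-wave maximum. Ripples are local maxima of the
#' 120-300 Hz band-passed raw trace exceeding 3 x its (whole-trace) SD,
#' analyzed in a 25 ms window around the sharp-wave maximum.
#'
#' @param sw_lowpass_hz sharp-wave lowpass cutoff (default 45).
#' @param sw_threshold_sd sharp-wave detection threshold in SD units (2.5).
#' @param min_interval_ms minimum interval between events (80).
#' @param sw_window_ms sharp-wave analysis window length (125).
#' @param ripple_band_hz ripple band edges (c(120, 300)).
#' @param ripple_threshold_sd ripple detection threshold in SD units (3).
#' @param ripple_window_ms ripple analysis window length (25).
#' @param polarity \code{"absolute"} (default: deflections of either sign
#'   relative to the mean), \code{"positive"} or \code{"negative"}.
#' @return list of class \code{swr_params}.
#' @export
swr_params <- function(sw_lowpass_hz = 45, sw_threshold_sd = 2.5,
                       min_interval_ms = 80, sw_window_ms = 125,
                       ripple_band_hz = c(120, 300),
                       ripple_threshold_sd = 3, ripple_window_ms = 25,
                       polarity = c("absolute", "positive", "negative")) {
  polarity <- match.arg(polarity)
  if (sw_threshold_sd <= 0 || ripple_threshold_sd <= 0)
    stop("thresholds must be positive")
  if (min_interval_ms <= 0 || sw_window_ms <= 0 || ripple_window_ms <= 0)
    stop("windows and intervals must be positive")
  if (!(ripple_band_hz[1] > 0 && ripple_band_hz[1] < ripple_band_hz[2]))
    stop("invalid ripple band")
  structure(list(sw_lowpass_hz = sw_lowpass_hz,
                 sw_threshold_sd = sw_threshold_sd,
                 min_interval_ms = min_interval_ms,
                 sw_window_ms = sw_window_ms,
                 ripple_band_hz = ripple_band_hz,
                 ripple_threshold_sd = ripple_threshold_sd,
                 ripple_window_ms = ripple_window_ms,
                 polarity = polarity),
            class = "swr_params")
}

# polarity-resolved deviation of the low-passed trace from its mean
sw_detection_signal <- function(rec, params) {
  lp <- lowpass(rec, params$sw_lowpass_hz)
  x <- lp$samples - mean(lp$samples)
  d <- switch(params$polarity,
              absolute = abs(x),
              positive = x,
              negative = -x)
  list(d = d, x = x, sd = stats::sd(x))
}

#' Detect sharp-wave events
#'
#' Candidate peaks are local maxima of the polarity-resolved, 45 Hz
#' low-passed, mean-subtracted trace exceeding \code{sw_threshold_sd} times
#' the SD of that filtered trace (SD taken over the whole trace). The 80 ms
#' minimum-interval rule is enforced by keeping the larger-amplitude peak of
#' any conflicting pair; events whose 125 ms window would cross the trace
#' boundary are discarded.
#'
#' @param rec raw \code{\link{lfp_recording}}.
#' @param params an \code{\link{swr_params}}.
#' @return data.frame with \code{peak_index}, \code{peak_time_s},
#'   \code{amplitude_mv} (polarity-resolved deviation from the mean), sorted
#'   by time. A zero-variance trace yields zero events.
#' @export
detect_sharp_waves <- function(rec, params = swr_params()) {
  stopifnot_recording(rec)
  win <- as.integer(round(params$sw_window_ms / 1000 * rec$fs_hz))
  if (length(rec$samples) < win)
    stop("trace shorter than one sharp-wave analysis window")
  sig <- sw_detection_signal(rec, params)
  empty <- data.frame(peak_index = integer(0), peak_time_s = numeric(0),
                      amplitude_mv = numeric(0))
  if (sig$sd == 0) return(empty)
  thr <- params$sw_threshold_sd * sig$sd
  cand <- local_maxima(sig$d)
  cand <- cand[sig$d[cand] > thr]
  if (!length(cand)) return(empty)
  # larger-amplitude peak wins any conflict under the minimum-interval rule
  min_gap <- params$min_interval_ms / 1000 * rec$fs_hz
  ord <- cand[order(sig$d[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(kept - i) >= min_gap)) kept <- c(kept, i)
  }
  half <- win %/% 2L
  kept <- kept[kept - half >= 1L & kept + half <= length(rec$samples)]
  kept <- sort(kept)
  data.frame(peak_index = kept,
             peak_time_s = rec$t0_s + (kept - 1L) / rec$fs_hz,
             amplitude_mv = sig$d[kept])
}

#' Sharp-wave area between mean crossings
#'
#' Trapezoidal integral of (signal - window mean) from the last
#' mean-crossing before the peak to the first mean-crossing after it, on the
#' polarity-resolved low-pass-filtered 125 ms event window. If a crossing is
#' missing on either side the integration runs to the window edge and the
#' result is flagged.
#'
#' @param window numeric vector: polarity-resolved low-passed data stretch
#'   centered on the sharp-wave maximum (peak at the central sample).
#' @param fs_hz sampling rate of the window.
#' @param window_mean mean used as the crossing baseline; defaults to the
#'   mean of \code{window}.
#' @return list with \code{area_mv_ms} (nonnegative) and
#'   \code{edge_flag} (TRUE when a crossing was missing).
#' @export
sw_area <- function(window, fs_hz, window_mean = mean(window)) {
  n <- length(window)
  if (n < 3L) stop("window too short")
  peak <- (n + 1L) %/% 2L
  y <- window - window_mean
  below <- y <= 0
  left <- peak; flag_l <- FALSE
  while (left > 1L && !below[left - 1L]) left <- left - 1L
  if (left == 1L && !below[1L]) flag_l <- TRUE
  right <- peak; flag_r <- FALSE
  while (right < n && !below[right + 1L]) right <- right + 1L
  if (right == n && !below[n]) flag_r <- TRUE
  # extend one sample into the crossing so the trapezoid includes it
  lo <- max(1L, left - 1L); hi <- min(n, right + 1L)
  seg <- pmax(y[lo:hi], 0)          # clip the sub-baseline crossing samples
  dt_ms <- 1000 / fs_hz
  area <- sum((seg[-1] + seg[-length(seg)]) / 2) * dt_ms
  list(area_mv_ms = max(area, 0), edge_flag = flag_l || flag_r)
}

# extract a window of len_ms centered on index i (assumes it fits)
centered_window <- function(x, i, len_ms, fs_hz) {
  half <- as.integer(round(len_ms / 1000 * fs_hz)) %/% 2L
  x[(i - half):(i + half)]
}

#' Ripple metrics for one sharp-wave event
#'
#' The raw trace is band-pass filtered (120-300 Hz); within the 25 ms window
#' centered on the sharp-wave maximum, ripple peaks are band-passed local
#' maxima exceeding \code{ripple_threshold_sd} times the SD of the
#' band-passed whole trace (the threshold is global, not per-window).
#' Per-ripple amplitude is the mean of its rising (peak minus preceding
#' trough) and falling (peak minus following trough) components; the event
#' amplitude is the mean over ripples. Ripple frequency is the mean of the
#' reciprocal inter-peak intervals of consecutive ripples and is therefore
#' only defined when at least two ripples are present. Troughs missing
#' inside the window fall back to the window edge minimum and flag the event
#' as edge-truncated.
#'
#' @param rec raw \code{\link{lfp_recording}}.
#' @param peak_index sample index of the sharp-wave maximum.
#' @param params an \code{\link{swr_params}}.
#' @param band_rec optional precomputed band-passed recording (re-used across
#'   events of the same trace).
#' @param band_sd optional precomputed global SD of the band-passed trace.
#' @return list with \code{ripple_count}, \code{ripple_amplitude_mv} (NA if
#'   no ripples), \code{ripple_frequency_hz} (NA if fewer than 2 ripples),
#'   \code{edge_flag}.
#' @export
analyze_ripples <- function(rec, peak_index, params = swr_params(),
                            band_rec = NULL, band_sd = NULL) {
  stopifnot_recording(rec)
  if (is.null(band_rec))
    band_rec <- bandpass(rec, params$ripple_band_hz[1], params$ripple_band_hz[2])
  if (is.null(band_sd)) band_sd <- stats::sd(band_rec$samples)
  half <- as.integer(round(params$ripple_window_ms / 1000 * rec$fs_hz)) %/% 2L
  lo <- max(1L, peak_index - half)
  hi <- min(length(rec$samples), peak_index + half)
  w <- band_rec$samples[lo:hi]
  thr <- params$ripple_threshold_sd * band_sd
  peaks <- local_maxima(w)
  peaks <- peaks[w[peaks] > thr]
  none <- list(ripple_count = 0L, ripple_amplitude_mv = NA_real_,
               ripple_frequency_hz = NA_real_, edge_flag = FALSE)
  if (!length(peaks)) return(none)
  troughs <- local_maxima(-w)       # local minima
  edge_flag <- FALSE
  amp <- vapply(peaks, function(p) {
    prev <- troughs[troughs < p]
    nxt <- troughs[troughs > p]
    if (!length(prev)) { prev <- which.min(w[1:p]); edge_flag <<- TRUE }
    else prev <- max(prev)
    if (!length(nxt)) { nxt <- p - 1L + which.min(w[p:length(w)]); edge_flag <<- TRUE }
    else nxt <- min(nxt)
    rising <- w[p] - w[prev]
    falling <- w[p] - w[nxt]
    (rising + falling) / 2
  }, numeric(1))
  freq <- if (length(peaks) >= 2L) {
    # parabolic sub-sample refinement of peak positions for the intervals
    refined <- vapply(peaks, function(p) {
      if (p <= 1L || p >= length(w)) return(as.numeric(p))
      den <- w[p - 1L] - 2 * w[p] + w[p + 1L]
      if (den >= 0) return(as.numeric(p))
      p + 0.5 * (w[p - 1L] - w[p + 1L]) / den
    }, numeric(1))
    mean(1 / (diff(refined) / rec$fs_hz))
  } else NA_real_
  list(ripple_count = length(peaks), ripple_amplitude_mv = mean(amp),
       ripple_frequency_hz = freq, edge_flag = edge_flag)
}

#' Full sharp-wave ripple analysis of one recording
#'
#' Runs \code{\link{detect_sharp_waves}}, then quantifies every event:
#' sharp-wave area (\code{\link{sw_area}} on the 125 ms low-passed window)
#' and ripple metrics (\code{\link{analyze_ripples}} on the 25 ms
#' band-passed window).
#'
#' @param rec raw \code{\link{lfp_recording}}.
#' @param params an \code{\link{swr_params}}.
#' @return data.frame with one row per event: \code{peak_time_s},
#'   \code{sw_area_mv_ms}, \code{ripple_count}, \code{ripple_amplitude_mv},
#'   \code{ripple_frequency_hz}, \code{flags}.
#' @export
analyze_swr <- function(rec, params = swr_params()) {
  ev <- detect_sharp_waves(rec, params)
  out <- data.frame(peak_time_s = ev$peak_time_s,
                    sw_area_mv_ms = numeric(nrow(ev)),
                    ripple_count = integer(nrow(ev)),
                    ripple_amplitude_mv = numeric(nrow(ev)),
                    ripple_frequency_hz = numeric(nrow(ev)),
                    flags = character(nrow(ev)),
                    stringsAsFactors = FALSE)
  if (!nrow(ev)) return(out)
  sig <- sw_detection_signal(rec, params)
  band <- bandpass(rec, params$ripple_band_hz[1], params$ripple_band_hz[2])
  bsd <- stats::sd(band$samples)
  for (k in seq_len(nrow(ev))) {
    w <- centered_window(sig$d, ev$peak_index[k], params$sw_window_ms,
                         rec$fs_hz)
    ar <- sw_area(w, rec$fs_hz)
    rp <- analyze_ripples(rec, ev$peak_index[k], params, band, bsd)
    flags <- c(if (ar$edge_flag) "sw_area_edge",
               if (rp$edge_flag) "ripple_edge")
    out$sw_area_mv_ms[k] <- ar$area_mv_ms
    out$ripple_count[k] <- rp$ripple_count
    out$ripple_amplitude_mv[k] <- rp$ripple_amplitude_mv
    out$ripple_frequency_hz[k] <- rp$ripple_frequency_hz
    out$flags[k] <- paste(flags, collapse = ";")
  }
  out
}

#' Per-slice sharp-wave ripple summary
#'
#' @param events data.frame from \code{\link{analyze_swr}}.
#' @param duration_s recording duration in seconds (> 0).
#' @return list with \code{n_events}, \code{incidence_per_s},
#'   \code{mean_sw_area_mv_ms}, \code{mean_ripple_amplitude_mv},
#'   \code{mean_ripple_frequency_hz}; means over events ignore absent (NA)
#'   fields and are NA when no event contributes.
#' @export
swr_summary <- function(events, duration_s) {
  if (duration_s <= 0) stop("duration_s must be positive")
  mean_or_na <- function(x) if (all(is.na(x)) || !length(x)) NA_real_
                            else mean(x, na.rm = TRUE)
  list(n_events = nrow(events),
       incidence_per_s = nrow(events) / duration_s,
       mean_sw_area_mv_ms = mean_or_na(events$sw_area_mv_ms),
       mean_ripple_amplitude_mv = mean_or_na(events$ripple_amplitude_mv),
       mean_ripple_frequency_hz = mean_or_na(events$ripple_frequency_hz))
}
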