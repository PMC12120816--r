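#' Construct an evoked fEPSP sweep
#'
#' @param samples voltage trace in mV.
#' @param fs_hz sampling rate.
#' @param stim_times_s one or two stimulus onsets (seconds from sweep start).
#'   For paired sweeps the interstimulus interval must be one of 10, 20, 50,
#'   100 or 200 ms.
#' @param stim_intensity_ua stimulation intensity in microamps.
#' @param timestamp_s position of the sweep in the experiment, seconds
#'   (HFS convention: induction at 0).
#' @return object of class \code{fepsp_sweep}.
#' @export
fepsp_sweep <- function(samples, fs_hz, stim_times_s,
                        stim_intensity_ua = NA_real_, timestamp_s = 0) {
  samples <- as.numeric(samples)
  if (anyNA(samples)) stop("sweep contains missing values")
  dur <- length(samples) / fs_hz
  if (!length(stim_times_s) %in% 1:2) stop("one or two stimulus times required")
  if (any(stim_times_s < 0 | stim_times_s >= dur))
    stop("stimulus times must lie within the sweep")
  if (length(stim_times_s) == 2L) {
    isi_ms <- round((stim_times_s[2] - stim_times_s[1]) * 1000, 6)
    if (!isi_ms %in% c(10, 20, 50, 100, 200))
      stop("interstimulus interval must be one of 10, 20, 50, 100, 200 ms")
  }
  structure(list(samples = samples, fs_hz = as.numeric(fs_hz),
                 stim_times_s = as.numeric(stim_times_s),
                 stim_intensity_ua = as.numeric(stim_intensity_ua),
                 timestamp_s = as.numeric(timestamp_s)),
            class = "fepsp_sweep")
}

# slope of one response on a (possibly tail-corrected) trace segment.
# Returns list(slope_mv_ms, flagged). Measurement window: from stim + blank
# to `until_s` (or sweep end); the 20-80% span of the initial rising phase
# of the dominant deflection is fitted with a straight line.
measure_slope <- function(v, fs, stim_s, blank_ms = 1, frac = c(0.2, 0.8),
                          until_s = Inf, min_amp_mv = 0.01) {
  n <- length(v)
  i0 <- min(n, as.integer(round((stim_s + blank_ms / 1000) * fs)) + 1L)
  i1 <- min(n, as.integer(floor(min(until_s, n / fs) * fs)))
  if (i1 - i0 < 4L) return(list(slope_mv_ms = 0, flagged = TRUE))
  seg <- v[i0:i1]
  base <- seg[1L]                      # local baseline after blanking
  dev <- seg - base
  # cursor placement (peak, onset, 20-80% band) on a lightly smoothed copy,
  # so sample selection is not correlated with the noise; the line itself is
  # fitted on the raw samples
  k <- 5L
  sm <- stats::filter(dev, rep(1 / k, k), sides = 2)
  sm[is.na(sm)] <- dev[is.na(sm)]
  sm <- as.numeric(sm)
  ipk <- which.max(abs(sm))
  amp <- sm[ipk]
  if (abs(amp) < min_amp_mv || ipk < 3L)
    return(list(slope_mv_ms = 0, flagged = TRUE))
  rise <- sm[1:ipk] / amp              # normalized 0..1 rising phase
  # onset: last sample before the peak still below 5% of the peak amplitude
  below <- which(rise[1:(ipk - 1L)] <= 0.05)
  on <- if (length(below)) max(below) else 1L
  sel <- seq(on, ipk)
  sel <- sel[rise[sel] >= frac[1] & rise[sel] <= frac[2]]
  if (length(sel) < 2L) {              # very steep rise: fall back to secant
    lo <- max(on, ipk - 2L)
    sel <- seq(lo, ipk)
  }
  tt <- (sel - 1L) / fs * 1000         # ms
  fit <- stats::lm.fit(cbind(1, tt), dev[sel])
  list(slope_mv_ms = abs(fit$coefficients[[2]]), flagged = FALSE)
}

#' fEPSP initial slope
#'
#' Magnitude of the initial slope of the field EPSP, in mV/ms, reported
#' positive regardless of deflection sign. The stimulus artifact is removed
#' by a 1 ms blanking window after the stimulus; the slope is a straight-line
#' fit over the 20-80% span of the initial rising phase of the dominant
#' deflection. Sweeps without a detectable response (peak deflection below
#' 0.01 mV) return a flagged zero.
#'
#' @param sweep an \code{\link{fepsp_sweep}} (first stimulus is used).
#' @param blank_ms post-stimulus blanking, ms (default 1).
#' @param frac rising-phase fit span as fractions of the peak (default
#'   c(0.2, 0.8)).
#' @return list with \code{slope_mv_ms} and \code{flagged}.
#' @export
fepsp_slope <- function(sweep, blank_ms = 1, frac = c(0.2, 0.8)) {
  if (!inherits(sweep, "fepsp_sweep")) stop("expected an fepsp_sweep")
  until <- if (length(sweep$stim_times_s) == 2L) sweep$stim_times_s[2]
           else Inf
  measure_slope(sweep$samples, sweep$fs_hz, sweep$stim_times_s[1],
                blank_ms, frac, until_s = until)
}

#' Input-output curve
#'
#' Mean fEPSP slope per stimulation intensity, preserving intensity order.
#'
#' @param sweeps list of \code{\link{fepsp_sweep}} objects with
#'   \code{stim_intensity_ua} set.
#' @return data.frame with \code{stim_intensity_ua}, \code{mean_slope_mv_ms},
#'   \code{n}, ordered by intensity.
#' @export
io_curve <- function(sweeps) {
  slopes <- vapply(sweeps, function(s) fepsp_slope(s)$slope_mv_ms, numeric(1))
  ints <- vapply(sweeps, function(s) s$stim_intensity_ua, numeric(1))
  if (anyNA(ints)) stop("all sweeps need a stimulation intensity")
  agg <- stats::aggregate(slopes, list(stim_intensity_ua = ints), mean)
  cnt <- stats::aggregate(slopes, list(stim_intensity_ua = ints), length)
  out <- data.frame(stim_intensity_ua = agg$stim_intensity_ua,
                    mean_slope_mv_ms = agg$x, n = cnt$x)
  out[order(out$stim_intensity_ua), , drop = FALSE]
}

#' Half-maximal stimulation intensity
#'
#' The smallest tested intensity whose mean slope is closest to half the
#' maximal mean slope (ties resolved toward the lower intensity). A flat
#' (all-equal) curve returns the lowest intensity with a degenerate flag.
#'
#' @param curve data.frame from \code{\link{io_curve}}.
#' @return list with \code{intensity_ua} and \code{degenerate}.
#' @export
half_max_intensity <- function(curve) {
  if (!nrow(curve)) stop("empty input-output curve")
  s <- curve$mean_slope_mv_ms
  degen <- max(s) - min(s) <= .Machine$double.eps * max(abs(s), 1)
  target <- max(s) / 2
  err <- abs(s - target)
  i <- which(err <= min(err) + 1e-12)[1L]    # first index = lowest intensity
  list(intensity_ua = curve$stim_intensity_ua[i], degenerate = degen)
}

#' Paired-pulse ratio
#'
#' slope2 / slope1 for a two-stimulus sweep. Before measuring the second
#' response, the decaying tail of the first response is removed by
#' mono-exponential extrapolation fitted to the decay between the first
#' response's peak and the second stimulus (needed at short ISIs; skipped
#' when the tail is negligible).
#'
#' @param sweep an \code{\link{fepsp_sweep}} with two stimuli.
#' @return list with \code{ratio}, \code{isi_ms}, \code{slope1_mv_ms},
#'   \code{slope2_mv_ms}, \code{flagged} (TRUE when slope1 is ~0 and the
#'   ratio is undefined).
#' @export
paired_pulse_ratio <- function(sweep) {
  if (!inherits(sweep, "fepsp_sweep")) stop("expected an fepsp_sweep")
  if (length(sweep$stim_times_s) != 2L) stop("paired sweep requires two stimuli")
  fs <- sweep$fs_hz
  s1 <- sweep$stim_times_s[1]; s2 <- sweep$stim_times_s[2]
  isi_ms <- (s2 - s1) * 1000
  m1 <- measure_slope(sweep$samples, fs, s1, until_s = s2)
  if (m1$flagged || m1$slope_mv_ms <= 0)
    return(list(ratio = NA_real_, isi_ms = isi_ms,
                slope1_mv_ms = m1$slope_mv_ms, slope2_mv_ms = NA_real_,
                flagged = TRUE))
  v <- sweep$samples
  n <- length(v)
  # locate first response's peak between the stimuli
  j0 <- as.integer(round((s1 + 0.001) * fs)) + 1L
  j1 <- as.integer(round(s2 * fs))
  seg <- v[j0:j1] - v[j0]
  ipk <- j0 - 1L + which.max(abs(seg))
  base <- v[j0]
  tail_amp <- abs(v[j1] - base)
  if (tail_amp > 0.005 && j1 - ipk >= 5L) {
    # mono-exponential fit of the decay, on the dominant deflection sign
    dec <- v[ipk:j1] - base
    sgn <- sign(dec[1L])
    y <- sgn * dec
    ok <- which(y > max(y) * 0.02)
    if (length(ok) >= 5L) {
      tt <- (ok - 1L) / fs
      fit <- stats::lm.fit(cbind(1, tt), log(y[ok]))
      a <- exp(fit$coefficients[[1]]); tau <- -1 / fit$coefficients[[2]]
      if (is.finite(tau) && tau > 0) {
        t_ext <- (seq.int(ipk, n) - ipk) / fs
        v[ipk:n] <- v[ipk:n] - sgn * a * exp(-t_ext / tau)
      }
    }
  }
  m2 <- measure_slope(v, fs, s2)
  list(ratio = m2$slope_mv_ms / m1$slope_mv_ms, isi_ms = isi_ms,
       slope1_mv_ms = m1$slope_mv_ms, slope2_mv_ms = m2$slope_mv_ms,
       flagged = FALSE)
}

#' Normalize an LTP experiment to its baseline
#'
#' Computes per-sweep fEPSP slopes, expresses them as a percentage of the
#' mean slope over the baseline window before the HFS marker, and timestamps
#' them in minutes relative to HFS at 0.
#'
#' @param sweeps list of \code{\link{fepsp_sweep}} objects spanning the
#'   experiment.
#' @param hfs_time_s HFS marker in experiment time (seconds).
#' @param baseline_min baseline window length before HFS, minutes
#'   (default 10).
#' @return object of class \code{ltp_series}: data.frame with
#'   \code{time_min}, \code{slope_pct}; attributes \code{baseline_min},
#'   \code{baseline_mean_mv_ms}.
#' @export
ltp_normalize <- function(sweeps, hfs_time_s = 0, baseline_min = 10) {
  slopes <- vapply(sweeps, function(s) fepsp_slope(s)$slope_mv_ms, numeric(1))
  tmin <- vapply(sweeps, function(s) (s$timestamp_s - hfs_time_s) / 60,
                 numeric(1))
  bl <- tmin >= -baseline_min & tmin < 0
  if (!any(bl)) stop("no sweeps inside the baseline window")
  bmean <- mean(slopes[bl])
  if (bmean <= 0) stop("baseline mean slope is zero")
  out <- data.frame(time_min = tmin, slope_pct = slopes / bmean * 100)
  out <- out[order(out$time_min), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, baseline_min = baseline_min, baseline_mean_mv_ms = bmean,
            class = c("ltp_series", "data.frame"))
}

#' LTP summary over the final window
#'
#' Mean and SEM of the normalized slope over the last \code{last_window_min}
#' minutes of the series -- the standard endpoint for comparing potentiation
#' between conditions.
#'
#' @param series an \code{ltp_series} from \code{\link{ltp_normalize}}.
#' @param last_window_min window length (default 10).
#' @return list with \code{mean_pct}, \code{sem_pct}, \code{n}.
#' @export
ltp_summary <- function(series, last_window_min = 10) {
  post <- series[series$time_min > 0, , drop = FALSE]
  if (!nrow(post)) stop("series has no post-HFS sweeps")
  t_end <- max(post$time_min)
  w <- post[post$time_min >= t_end - last_window_min, , drop = FALSE]
  if (!nrow(w)) stop("empty final window")
  n <- nrow(w)
  list(mean_pct = mean(w$slope_pct),
       sem_pct = if (n > 1) stats::sd(w$slope_pct) / sqrt(n) else 0,
       n = n)
}
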