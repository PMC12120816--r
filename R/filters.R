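## Zero-phase filtering and spectral primitives shared by the SWR and gamma
## stages. Filters realize the magnitude response of a 4th-order Butterworth
## applied forward-backward (the de facto standard in the SWR literature).
## The response is applied in the frequency domain, which is exactly
## zero-phase by construction; reflect padding (~1 s each side) suppresses
## wrap-around transients at the trace edges.

# amplitude gain of an order-n Butterworth lowpass applied forward-backward
butter_lp_gain <- function(f, cutoff_hz, order) {
  1 / (1 + (f / cutoff_hz)^(2 * order))
}

# forward-backward gain of an order-n Butterworth bandpass prototype
butter_bp_gain <- function(f, lo_hz, hi_hz, order) {
  bw <- hi_hz - lo_hz
  f0sq <- lo_hz * hi_hz
  g <- numeric(length(f))
  nz <- f > 0
  x <- (f[nz]^2 - f0sq) / (f[nz] * bw)
  g[nz] <- 1 / (1 + x^(2 * order))
  g
}

# apply a real (zero-phase) frequency-domain gain with reflect padding
fft_apply_gain <- function(x, fs, gain_fun) {
  n <- length(x)
  pad <- min(n - 1L, as.integer(round(fs)))
  xp <- c(rev(x[2:(pad + 1L)]), x, rev(x[(n - pad):(n - 1L)]))
  m0 <- length(xp)
  m <- stats::nextn(m0, c(2L, 3L, 5L))
  xp <- c(xp, numeric(m - m0))
  f <- (seq_len(m) - 1L) / m * fs
  f <- pmin(f, fs - f)          # fold to [0, fs/2]
  g <- gain_fun(f)
  y <- Re(stats::fft(stats::fft(xp) * g, inverse = TRUE)) / m
  y[pad + seq_len(n)]
}

#' Zero-phase lowpass filter
#'
#' Applies the magnitude response of a 4th-order Butterworth lowpass run
#' forward and backward (zero phase: event peaks are not shifted in time).
#'
#' @param rec an \code{\link{lfp_recording}}.
#' @param cutoff_hz cutoff frequency, 0 < cutoff < fs/2. The sharp-wave
#'   detection stage uses 45 Hz; gamma correlograms use 100 Hz.
#' @param order filter order of the underlying one-pass Butterworth
#'   (default 4).
#' @return filtered \code{lfp_recording}.
#' @export
lowpass <- function(rec, cutoff_hz, order = 4L) {
  stopifnot_recording(rec)
  nyq <- rec$fs_hz / 2
  if (!(cutoff_hz > 0 && cutoff_hz < nyq))
    stop("cutoff_hz must lie in (0, fs/2)")
  y <- fft_apply_gain(rec$samples, rec$fs_hz,
                      function(f) butter_lp_gain(f, cutoff_hz, order))
  lfp_recording(y, rec$fs_hz, rec$t0_s, rec$label)
}

#' Zero-phase bandpass filter
#'
#' Forward-backward 4th-order Butterworth bandpass. The ripple stage uses the
#' 120-300 Hz band.
#'
#' @param rec an \code{\link{lfp_recording}}.
#' @param lo_hz,hi_hz band edges, 0 < lo < hi < fs/2.
#' @param order prototype order (default 4).
#' @return filtered \code{lfp_recording}.
#' @export
bandpass <- function(rec, lo_hz, hi_hz, order = 4L) {
  stopifnot_recording(rec)
  nyq <- rec$fs_hz / 2
  if (!(lo_hz > 0 && lo_hz < hi_hz)) stop("band edges must satisfy 0 < lo < hi")
  if (hi_hz >= nyq) stop("hi_hz must be below the Nyquist frequency")
  y <- fft_apply_gain(rec$samples, rec$fs_hz,
                      function(f) butter_bp_gain(f, lo_hz, hi_hz, order))
  lfp_recording(y, rec$fs_hz, rec$t0_s, rec$label)
}

#' Averaged-periodogram power spectrum
#'
#' Welch-style estimator: Hann-windowed segments of length
#' \code{round(fs / resolution_hz)} with 50\% overlap; windows that would
#' cross the trace boundary are dropped. Per-bin power is scaled so that the
#' sum over all bins equals the mean squared amplitude of a stationary input
#' (Parseval consistency); units are mV^2 per bin.
#'
#' @param rec an \code{\link{lfp_recording}}.
#' @param resolution_hz requested frequency resolution; the default 0.8192 Hz
#'   reproduces the acquisition software's FFT grid at 10 kHz (window length
#'   12207 samples).
#' @return object of class \code{lfp_spectrum}: list with \code{freqs_hz},
#'   \code{power_mv2}, \code{resolution_hz}, \code{n_windows}.
#' @export
power_spectrum <- function(rec, resolution_hz = 0.8192) {
  stopifnot_recording(rec)
  wlen <- as.integer(round(rec$fs_hz / resolution_hz))
  n <- length(rec$samples)
  if (n < wlen)
    stop(sprintf("recording (%d samples) shorter than one analysis window (%d)",
                 n, wlen))
  hop <- max(1L, wlen %/% 2L)
  starts <- seq.int(1L, n - wlen + 1L, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * seq.int(0L, wlen - 1L) / (wlen - 1L)) # Hann
  u <- sum(w^2)
  nb <- wlen %/% 2L + 1L
  acc <- numeric(nb)
  for (s in starts) {
    seg <- rec$samples[s:(s + wlen - 1L)]
    X <- stats::fft(seg * w)[seq_len(nb)]
    acc <- acc + Mod(X)^2
  }
  pxx <- acc / (length(starts) * u * wlen)   # two-sided power per bin
  # fold negative frequencies onto positive bins (one-sided)
  one <- pxx
  inner <- 2L:(nb - 1L)
  if (wlen %% 2L == 0L) inner <- inner[-length(inner)] # keep Nyquist unfolded
  one[inner] <- 2 * one[inner]
  if (wlen %% 2L != 0L) one[nb] <- 2 * one[nb]
  structure(
    list(freqs_hz = (seq_len(nb) - 1L) * rec$fs_hz / wlen,
         power_mv2 = one,
         resolution_hz = rec$fs_hz / wlen,
         n_windows = length(starts)),
    class = "lfp_spectrum")
}

#' @export
print.lfp_spectrum <- function(x, ...) {
  cat(sprintf("<lfp_spectrum> %d bins, df = %.4f Hz, %d windows, total power %.4g mV^2\n",
              length(x$freqs_hz), x$resolution_hz, x$n_windows,
              sum(x$power_mv2)))
  invisible(x)
}

#' @export
as.data.frame.lfp_spectrum <- function(x, ...) {
  data.frame(freq_hz = x$freqs_hz, power_mv2 = x$power_mv2)
}

#' Normalized autocorrelation (correlogram)
#'
#' Biased FFT autocorrelation of the mean-subtracted trace, normalized so the
#' lag-0 coefficient is exactly 1; only nonnegative lags are returned.
#' Callers targeting the gamma rhythmicity statistic should lowpass at
#' 100 Hz first (see \code{\link{autocorr_second_peak}}).
#'
#' @param rec an \code{\link{lfp_recording}}.
#' @param max_lag_s largest lag to return, must be smaller than the duration.
#' @return data.frame with columns \code{lag_s} and \code{r} (in [-1, 1]).
#' @export
autocorrelation <- function(rec, max_lag_s) {
  stopifnot_recording(rec)
  if (max_lag_s >= lfp_duration(rec)) stop("max_lag_s must be below the duration")
  x <- rec$samples - mean(rec$samples)
  n <- length(x)
  lmax <- as.integer(floor(max_lag_s * rec$fs_hz))
  m <- stats::nextn(n + lmax, c(2L, 3L, 5L))
  X <- stats::fft(c(x, numeric(m - n)))
  r <- Re(stats::fft(Mod(X)^2, inverse = TRUE))[seq_len(lmax + 1L)] / m
  if (r[1L] <= 0) {            # zero-variance trace: define r = 0 beyond lag 0
    r <- c(1, numeric(lmax))
  } else {
    r <- r / r[1L]
  }
  data.frame(lag_s = seq.int(0L, lmax) / rec$fs_hz, r = r)
}

# indices of strict-rise / non-strict-fall local maxima of a vector
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  i[x[i] > x[i - 1L] & x[i] >= x[i + 1L]]
}
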