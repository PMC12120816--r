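#' Construct a field-potential recording
#'
#' A uniformly sampled single-channel local field potential (or field
#' potential) trace in millivolts. This is the substrate of the sharp-wave
#' ripple and gamma analyses.
#'
#' @param samples numeric vector of amplitudes (mV), length >= 2, no NAs.
#' @param fs_hz sampling rate in samples/second (> 0). Recordings in the
#'   target acquisition regime are digitized at 10 kHz.
#' @param t0_s start time of the first sample, seconds.
#' @param label free-text label carried through analyses.
#' @return object of class \code{lfp_recording}.
#' @export
lfp_recording <- function(samples, fs_hz, t0_s = 0, label = "") {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) stop("recording needs at least 2 samples")
  if (anyNA(samples)) stop("recording contains missing values")
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || fs_hz <= 0)
    stop("fs_hz must be a single positive number")
  structure(
    list(samples = samples, fs_hz = as.numeric(fs_hz),
         t0_s = as.numeric(t0_s), label = as.character(label)),
    class = "lfp_recording")
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> %s%.3f s @ %g Hz (%d samples), %.4g mV RMS\n",
              if (nzchar(x$label)) paste0(x$label, ": ") else "",
              lfp_duration(x), x$fs_hz, length(x$samples),
              sqrt(mean(x$samples^2))))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an \code{lfp_recording}.
#' @return duration in seconds (n / fs).
#' @export
lfp_duration <- function(rec) length(rec$samples) / rec$fs_hz

#' Time stamps of a recording
#' @param rec an \code{lfp_recording}.
#' @return numeric vector of per-sample times in seconds.
#' @export
lfp_times <- function(rec) rec$t0_s + (seq_along(rec$samples) - 1) / rec$fs_hz

#' @export
as.data.frame.lfp_recording <- function(x, ...) {
  data.frame(time_s = lfp_times(x), mv = x$samples)
}

stopifnot_recording <- function(rec) {
  if (!inherits(rec, "lfp_recording")) stop("expected an lfp_recording")
  invisible(rec)
}
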