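## Readers and writers for the package's plain-text exchange formats:
## LFP traces as CSV (time_s, mv) or raw little-endian float32 with a JSON
## sidecar; spectra and correlograms as CSV; images as headerless CSV
## matrices; ROIs and ground truth as JSON.

#' Write / read an LFP trace as CSV
#'
#' Columns \code{time_s}, \code{mv}. The reader infers the sampling rate
#' from the median time step.
#'
#' @param rec an \code{\link{lfp_recording}}.
#' @param path file path.
#' @return \code{read_lfp_csv} returns an \code{lfp_recording};
#'   \code{write_lfp_csv} returns \code{path} invisibly.
#' @export
write_lfp_csv <- function(rec, path) {
  stopifnot_recording(rec)
  utils::write.csv(as.data.frame(rec), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lfp_csv
#' @export
read_lfp_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "mv") %in% names(df))) stop("need columns time_s, mv")
  fs <- 1 / stats::median(diff(df$time_s))
  lfp_recording(df$mv, fs, t0_s = df$time_s[1], label = basename(path))
}

#' Write / read an LFP trace as raw float32 with a JSON sidecar
#'
#' Samples as little-endian 32-bit floats at \code{path}; metadata
#' (\code{fs_hz}, \code{units}, \code{duration_s}, \code{t0_s}) as JSON at
#' \code{paste0(path, ".json")}.
#'
#' @param rec an \code{\link{lfp_recording}}.
#' @param path binary file path (sidecar path derived from it).
#' @return \code{read_lfp_bin} returns an \code{lfp_recording}.
#' @export
write_lfp_bin <- function(rec, path) {
  stopifnot_recording(rec)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(rec$samples, con, size = 4L, endian = "little")
  jsonlite::write_json(list(fs_hz = rec$fs_hz, units = "mV",
                            duration_s = lfp_duration(rec), t0_s = rec$t0_s),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lfp_bin
#' @export
read_lfp_bin <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- as.integer(round(meta$duration_s * meta$fs_hz))
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, numeric(), n = n, size = 4L, endian = "little")
  lfp_recording(x, meta$fs_hz, t0_s = meta$t0_s %||% 0,
                label = basename(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a power spectrum as CSV
#' @param spec an \code{lfp_spectrum}.
#' @param path file path.
#' @export
write_spectrum_csv <- function(spec, path) {
  utils::write.csv(as.data.frame(spec), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  df <- utils::read.csv(path)
  structure(list(freqs_hz = df$freq_hz, power_mv2 = df$power_mv2,
                 resolution_hz = stats::median(diff(df$freq_hz)),
                 n_windows = NA_integer_),
            class = "lfp_spectrum")
}

#' Write / read an intensity image as a headerless CSV matrix
#' @param image numeric matrix (row = y).
#' @param path file path.
#' @export
write_image_csv <- function(image, path) {
  utils::write.table(image, path, row.names = FALSE, col.names = FALSE,
                     sep = ",")
  invisible(path)
}

#' @rdname write_image_csv
#' @export
read_image_csv <- function(path) {
  as.matrix(utils::read.csv(path, header = FALSE))
}

#' Write / read ROI polygons as JSON
#'
#' A list of polygons; each polygon is a list with \code{x} and \code{y}
#' vertex vectors in 0-based, y-down pixel coordinates.
#'
#' @param rois list of polygons.
#' @param path file path.
#' @export
write_rois_json <- function(rois, path) {
  jsonlite::write_json(rois, path, digits = NA)
  invisible(path)
}

#' @rdname write_rois_json
#' @export
read_rois_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

#' Write / read simulation ground truth as JSON
#' @param truth a ground-truth list as returned by the simulators.
#' @param path file path.
#' @export
write_ground_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_ground_truth_json
#' @export
read_ground_truth_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
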