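#' Multichannel continuous recording
#'
#' Container for a channels-by-samples matrix of continuous signal with a
#' sampling rate. Amplitude units are arbitrary: event detection
#' standardizes each channel, so gain and offset do not matter downstream.
#'
#' @param data numeric matrix, channels in rows, samples in columns.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param channel_labels optional character vector of channel names;
#'   defaults to `ch1 ... chN`.
#' @return An object of class `mscr_recording`: a list with elements
#'   `data`, `sampling_rate`, `channel_labels`.
#' @examples
#' rec <- recording(matrix(rnorm(500), nrow = 5), sampling_rate = 250)
#' rec
#' @export
recording <- function(data, sampling_rate, channel_labels = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      is.na(sampling_rate) || sampling_rate <= 0)
    stop("'sampling_rate' must be a single positive number")
  if (nrow(data) < 2L || ncol(data) < 2L)
    stop("a recording needs at least 2 channels and 2 samples")
  if (anyNA(data)) stop("recording data must not contain missing values")
  if (is.null(channel_labels)) {
    channel_labels <- if (!is.null(rownames(data))) rownames(data)
                      else paste0("ch", seq_len(nrow(data)))
  }
  if (length(channel_labels) != nrow(data))
    stop("'channel_labels' length must equal the number of channels")
  structure(
    list(data = data, sampling_rate = as.numeric(sampling_rate),
         channel_labels = as.character(channel_labels)),
    class = "mscr_recording")
}

#' @export
print.mscr_recording <- function(x, ...) {
  cat(sprintf("<mscr_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$sampling_rate,
              ncol(x$data) / x$sampling_rate))
  invisible(x)
}

#' Read a recording from a delimited text matrix
#'
#' Rows are channels, columns are samples. An optional leading column of
#' channel labels (non-numeric first field) is detected automatically.
#'
#' @param path path to the delimited file.
#' @param sampling_rate sampling rate in Hz (text files carry none).
#' @param sep field separator, default any whitespace.
#' @return An [recording()] object.
#' @export
read_recording_delim <- function(path, sampling_rate, sep = "") {
  raw <- utils::read.table(path, header = FALSE, sep = sep,
                           stringsAsFactors = FALSE)
  labels <- NULL
  if (!is.numeric(raw[[1L]])) {
    labels <- as.character(raw[[1L]])
    raw <- raw[, -1L, drop = FALSE]
  }
  mat <- as.matrix(raw)
  storage.mode(mat) <- "double"
  dimnames(mat) <- NULL
  recording(mat, sampling_rate, channel_labels = labels)
}

#' Write a recording as a delimited text matrix
#'
#' @param rec an [recording()] object.
#' @param path output path.
#' @param labels include the channel-label column? Default `TRUE`.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_recording_delim <- function(rec, path, labels = TRUE, sep = "\t") {
  stopifnot(inherits(rec, "mscr_recording"))
  out <- if (labels) data.frame(rec$channel_labels, rec$data,
                                check.names = FALSE)
         else as.data.frame(rec$data)
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Decimate a recording to a lower sampling rate
#'
#' Applies a zero-phase order-8 Butterworth low-pass at 0.8 times the
#' target Nyquist frequency (anti-aliasing), then resamples by linear
#' interpolation at the new sample times. The target rate need not divide
#' the original rate.
#'
#' @param rec an [recording()] object.
#' @param target_rate new sampling rate in Hz; must not exceed the
#'   current rate.
#' @return A new [recording()] at `target_rate`.
#' @examples
#' rec <- recording(matrix(rnorm(4000), nrow = 4), sampling_rate = 1000)
#' dec <- decimate_recording(rec, 250)
#' dec$sampling_rate
#' @export
decimate_recording <- function(rec, target_rate) {
  stopifnot(inherits(rec, "mscr_recording"))
  if (!is.numeric(target_rate) || length(target_rate) != 1L ||
      is.na(target_rate) || target_rate <= 0)
    stop("'target_rate' must be a single positive number")
  if (target_rate > rec$sampling_rate)
    stop("'target_rate' exceeds the recording's sampling rate")
  if (target_rate == rec$sampling_rate) return(rec)
  ratio <- target_rate / rec$sampling_rate
  bf <- signal::butter(8, 0.8 * ratio)
  n_in <- ncol(rec$data)
  n_out <- floor(n_in * ratio)
  t_new <- 1 + (seq_len(n_out) - 1) / ratio
  out <- t(apply(rec$data, 1L, function(x) {
    xf <- signal::filtfilt(bf, x)
    stats::approx(seq_len(n_in), xf, xout = t_new)$y
  }))
  recording(out, target_rate, rec$channel_labels)
}
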