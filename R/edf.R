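# Minimal EDF (European Data Format) I/O: fixed-layout ASCII header plus
# 16-bit little-endian data records. Covers continuous multichannel
# recordings with one common sampling rate; annotations channels and
# discontinuous (EDF+D) files are out of scope.

#' Read a continuous EDF biosignal file
#'
#' Parses the EDF header and data records and returns the signal scaled
#' to physical units via each channel's physical/digital calibration.
#' All channels must share one sampling rate.
#'
#' @param path path to the EDF file.
#' @return An [recording()] object; the header fields are attached as
#'   attribute `edf_header`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_txt <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  version <- hdr_txt(8L)
  patient <- hdr_txt(80L); rec_id <- hdr_txt(80L)
  start_date <- hdr_txt(8L); start_time <- hdr_txt(8L)
  header_bytes <- as.integer(hdr_txt(8L))
  reserved <- hdr_txt(44L)
  n_records <- as.integer(hdr_txt(8L))
  record_dur <- as.numeric(hdr_txt(8L))
  ns <- as.integer(hdr_txt(4L))
  if (is.na(ns) || ns < 1L) stop("not a valid EDF file: bad signal count")
  fld <- function(w) vapply(seq_len(ns), function(i) hdr_txt(w), character(1))
  labels <- fld(16L); transducer <- fld(80L); phys_dim <- fld(8L)
  phys_min <- as.numeric(fld(8L)); phys_max <- as.numeric(fld(8L))
  dig_min <- as.numeric(fld(8L)); dig_max <- as.numeric(fld(8L))
  prefilter <- fld(80L)
  nr <- as.integer(fld(8L))   # samples per record per signal
  fld(32L)                    # per-signal reserved
  if (length(unique(nr)) != 1L)
    stop("channels with differing sampling rates are not supported")
  if (record_dur <= 0) stop("non-positive record duration")
  fs <- nr[1L] / record_dur
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  data <- matrix(0, nrow = ns, ncol = n_records * nr[1L])
  for (r in seq_len(n_records)) {
    block <- readBin(con, "integer", n = ns * nr[1L], size = 2L,
                     signed = TRUE, endian = "little")
    cols <- ((r - 1L) * nr[1L] + 1L):(r * nr[1L])
    m <- matrix(block, nrow = nr[1L], ncol = ns)  # signal-major in record
    data[, cols] <- t(m) * gain + (phys_min - dig_min * gain)
  }
  rec <- recording(data, fs, channel_labels = labels)
  attr(rec, "edf_header") <- list(
    version = version, patient = patient, recording = rec_id,
    start_date = start_date, start_time = start_time,
    n_records = n_records, record_duration = record_dur,
    physical_dimension = phys_dim, transducer = transducer,
    prefilter = prefilter, reserved = reserved,
    header_bytes = header_bytes)
  rec
}

#' Write a recording as a continuous EDF file
#'
#' Encodes each channel with full 16-bit range calibration (physical
#' range = observed signal range). Samples are split into one-second
#' data records; a trailing partial second is zero-padded.
#'
#' @param rec an [recording()] object.
#' @param path output path.
#' @param phys_dim physical dimension string stored per channel.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, phys_dim = "uV") {
  stopifnot(inherits(rec, "mscr_recording"))
  ns <- nrow(rec$data)
  nr <- as.integer(round(rec$sampling_rate))
  if (abs(nr - rec$sampling_rate) > 1e-9)
    stop("write_edf() needs an integer sampling rate (1-second records)")
  n_records <- as.integer(ceiling(ncol(rec$data) / nr))
  pad <- n_records * nr - ncol(rec$data)
  data <- cbind(rec$data, matrix(0, ns, pad))
  phys_min <- apply(data, 1L, min); phys_max <- apply(data, 1L, max)
  flat <- phys_max == phys_min
  phys_max[flat] <- phys_min[flat] + 1
  dig_min <- -32768; dig_max <- 32767
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  dig <- round((data - phys_min) / gain + dig_min)

  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(x, w) {
    s <- formatC(as.character(x), width = -w)
    s <- vapply(s, function(si) substr(si, 1L, w), character(1))
    writeBin(charToRaw(paste(s, collapse = "")), con)
  }
  put("0", 8L)
  put("X X X X", 80L); put("mscrit export", 80L)
  put("01.01.00", 8L); put("00.00.00", 8L)
  put(as.character(256L * (1L + ns)), 8L)
  put("", 44L)
  put(as.character(n_records), 8L)
  put("1", 8L)
  put(as.character(ns), 4L)
  putv <- function(x, w) for (xi in x) put(xi, w)
  putv(rec$channel_labels, 16L)
  putv(rep("", ns), 80L)
  putv(rep(phys_dim, ns), 8L)
  numv <- function(x, w) putv(formatC(x, width = 1, format = "g", digits = 7), w)
  numv(phys_min, 8L); numv(phys_max, 8L)
  numv(rep(dig_min, ns), 8L); numv(rep(dig_max, ns), 8L)
  putv(rep("", ns), 80L)
  putv(rep(as.character(nr), ns), 8L)
  putv(rep("", ns), 32L)
  for (r in seq_len(n_records)) {
    cols <- ((r - 1L) * nr + 1L):(r * nr)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con, size = 2L,
             endian = "little")
  }
  invisible(path)
}
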