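#' Event raster
#'
#' Binary channels-by-bins matrix of suprathreshold events at a given
#' temporal bin width (an integer multiple k of the base sampling
#' interval), plus the per-bin count of base-resolution events. The binary
#' matrix is stored sparse; `base_counts` keeps the total number of
#' base-interval events falling into each (possibly coarse) bin, summed
#' over channels, so avalanche sizes remain comparable across scales.
#'
#' @param events sparse or dense binary matrix, channels x bins.
#' @param base_counts integer vector, one entry per bin: base-interval
#'   events summed over channels.
#' @param base_dt base sampling interval in seconds.
#' @param k coarse-graining factor (bin width = k * base_dt).
#' @param threshold detection threshold in channel-standard-deviation
#'   units, or `NA` for rasters not produced by thresholding.
#' @param channel_labels optional channel names.
#' @return An object of class `event_raster`.
#' @export
event_raster <- function(events, base_counts, base_dt, k = 1L,
                         threshold = NA_real_, channel_labels = NULL) {
  events <- methods::as(methods::as(Matrix::Matrix(events, sparse = TRUE),
                                    "dMatrix"), "CsparseMatrix")
  if (length(events@x) && any(events@x != 0 & events@x != 1))
    stop("'events' must be binary")
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("'k' must be an integer >= 1")
  if (base_dt <= 0) stop("'base_dt' must be positive")
  base_counts <- as.integer(base_counts)
  if (length(base_counts) != ncol(events))
    stop("'base_counts' must have one entry per bin")
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(nrow(events)))
  structure(
    list(events = events, base_counts = base_counts,
         base_dt = as.numeric(base_dt), k = k,
         threshold = as.numeric(threshold),
         channel_labels = as.character(channel_labels)),
    class = "event_raster")
}

#' @export
print.event_raster <- function(x, ...) {
  cat(sprintf(
    "<event_raster> %d channels x %d bins, k = %d (bin %.4g s), threshold = %s\n",
    nrow(x$events), ncol(x$events), x$k, x$k * x$base_dt,
    if (is.na(x$threshold)) "NA" else format(x$threshold)))
  cat(sprintf("  %d occupied channel-bins, %d base events\n",
              length(x$events@x), sum(x$base_counts)))
  invisible(x)
}

#' Detect suprathreshold events in a continuous recording
#'
#' Each channel is standardized to zero mean and unit standard deviation
#' over the whole recording. An excursion is a maximal run of samples with
#' `|x| > threshold` (both polarities); exactly one event is registered
#' per excursion, at the sample of maximal `|x|`. The returned raster is
#' at the base bin width (one bin per sample).
#'
#' Channels with zero variance cannot be standardized; they are flagged
#' with a warning and contribute no events.
#'
#' @param rec an [recording()] object.
#' @param threshold threshold in standard-deviation units (> 0).
#' @return An [event_raster()] with `k = 1`.
#' @examples
#' rec <- recording(matrix(rnorm(2000), nrow = 2), sampling_rate = 250)
#' r <- detect_events(rec, threshold = 3)
#' sum(r$base_counts)
#' @export
detect_events <- function(rec, threshold) {
  stopifnot(inherits(rec, "mscr_recording"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold <= 0)
    stop("'threshold' must be a single positive number")
  n_ch <- nrow(rec$data); n_s <- ncol(rec$data)
  ev_i <- vector("list", n_ch)
  for (i in seq_len(n_ch)) {
    x <- rec$data[i, ]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      warning(sprintf("channel %d ('%s') has zero variance; no events detected",
                      i, rec$channel_labels[i]))
      ev_i[[i]] <- integer(0)
      next
    }
    z <- abs((x - mean(x)) / s)
    ev_i[[i]] <- excursion_peaks(z, threshold)
  }
  ch <- rep.int(seq_len(n_ch), lengths(ev_i))
  bin <- unlist(ev_i, use.names = FALSE)
  events <- Matrix::sparseMatrix(i = ch, j = bin, x = 1,
                                 dims = c(n_ch, n_s))
  counts <- integer(n_s)
  if (length(bin)) {
    tb <- tabulate(bin, nbins = n_s)
    counts <- tb
  }
  event_raster(events, counts, base_dt = 1 / rec$sampling_rate, k = 1L,
               threshold = threshold, channel_labels = rec$channel_labels)
}

# indices of |z|-maxima, one per maximal run of z > thr
excursion_peaks <- function(z, thr) {
  above <- z > thr
  if (!any(above)) return(integer(0))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  vapply(keep, function(j) {
    i0 <- starts[j]
    i0 + which.max(z[i0:ends[j]]) - 1L
  }, integer(1))
}

#' Coarse-grain an event raster in time
#'
#' Merges k consecutive base bins into one coarse bin. The binary raster
#' is combined with a per-channel OR (a coarse channel-bin is occupied if
#' the channel had at least one event in the window); `base_counts` are
#' summed, so total base-event counts are preserved. A trailing partial
#' window is discarded.
#'
#' @param raster an [event_raster()] at the base bin width (`k = 1`).
#' @param k integer coarse-graining factor, >= 1.
#' @return An [event_raster()] with bin width `k * base_dt`.
#' @export
rebin_raster <- function(raster, k) {
  stopifnot(inherits(raster, "event_raster"))
  k <- suppressWarnings(as.integer(k))
  if (length(k) != 1L || is.na(k) || k < 1L)
    stop("'k' must be a single integer >= 1")
  if (raster$k != 1L)
    stop("'raster' must be at the base bin width (k = 1)")
  if (k == 1L) return(raster)
  n_bins <- ncol(raster$events)
  n_out <- n_bins %/% k
  if (n_out < 1L) stop("raster shorter than one coarse bin")
  used <- n_out * k
  win <- rep(seq_len(n_out), each = k)
  # per-channel OR via sparse matrix product with the window indicator
  agg <- Matrix::sparseMatrix(i = seq_len(used), j = win, x = 1,
                              dims = c(n_bins, n_out))
  ev <- raster$events %*% agg
  ev@x[] <- 1
  counts <- as.integer(rowsum(raster$base_counts[seq_len(used)], win))
  event_raster(ev, counts, base_dt = raster$base_dt, k = k,
               threshold = raster$threshold,
               channel_labels = raster$channel_labels)
}
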