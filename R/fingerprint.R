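MSCR_PARAMS <- c("sigma", "alpha", "tau", "gamma", "delta")

#' Canonical names of the 33 MsCr features
#'
#' Slope and intercept of the scale-dependence line of each of the five
#' criticality parameters (10 features), slope and intercept of the
#' curve of each unordered parameter pair (20 features; the first-listed
#' parameter is the abscissa), plus `kappa`, `kappa_gen` and `cutoff`
#' (3 features). Pair order follows the canonical parameter order
#' sigma, alpha, tau, gamma, delta.
#'
#' @return Character vector of length 33, in canonical order.
#' @examples
#' mscr_feature_names()
#' @export
mscr_feature_names <- function() {
  singles <- paste(rep(c("a", "b"), times = 5),
                   rep(MSCR_PARAMS, each = 2), sep = "_")
  prs <- utils::combn(MSCR_PARAMS, 2)
  pairs <- paste(rep(c("a", "b"), times = 10),
                 rep(paste(prs[1, ], prs[2, ], sep = "_"), each = 2),
                 sep = "_")
  c(singles, pairs, "kappa", "kappa_gen", "cutoff")
}

#' Exponent-versus-scale curves of a recording
#'
#' Runs the full avalanche analysis at each temporal scale k: the base
#' raster is detected once per threshold, coarse-grained by k, avalanches
#' are extracted per threshold and pooled, and the exponent profile is
#' computed from the pooled set. Scales with no avalanches produce
#' missing points in every curve.
#'
#' @param rec an [recording()] object (already at the base rate).
#' @param thresholds detection threshold grid in std units.
#' @param k_range integer scales (default 1:10).
#' @param config a [profile_config()].
#' @param base_k re-expresses the base bin width as `base_k` sampling
#'   intervals: scale k of the curve then corresponds to absolute scale
#'   `base_k * k`. Default 1. Doubling `base_k` should double fitted
#'   curve slopes and leave intercepts unchanged for linear curves.
#' @return An object of class `mscr_curves`: a list with `curves` (one
#'   data frame `k`/`value` per parameter), `profiles` (the
#'   `exponent_profile` at each k), `k_range`, `thresholds`.
#' @export
exponent_curves <- function(rec, thresholds, k_range = 1:10,
                            config = profile_config(), base_k = 1L) {
  stopifnot(inherits(rec, "mscr_recording"), length(thresholds) >= 1)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 1L)) stop("'k_range' must be positive integers")
  base_k <- as.integer(base_k)
  if (base_k < 1L) stop("'base_k' must be a positive integer")
  base_rasters <- lapply(thresholds, function(th) detect_events(rec, th))
  profiles <- lapply(k_range, function(k) {
    sets <- lapply(base_rasters, function(r)
      extract_avalanches(rebin_raster(r, base_k * k)))
    profile_at_scale(pool_avalanches(sets), config)
  })
  names(profiles) <- paste0("k", k_range)
  curves <- lapply(MSCR_PARAMS, function(p) {
    data.frame(k = k_range,
               value = vapply(profiles, `[[`, numeric(1), p))
  })
  names(curves) <- MSCR_PARAMS
  structure(list(curves = curves, profiles = profiles,
                 k_range = k_range, thresholds = thresholds),
            class = "mscr_curves")
}

#' @export
print.mscr_curves <- function(x, ...) {
  cat(sprintf("<mscr_curves> k = %s, thresholds = %s\n",
              paste(range(x$k_range), collapse = "-"),
              paste(x$thresholds, collapse = ", ")))
  tab <- sapply(x$curves, `[[`, "value")
  rownames(tab) <- paste0("k", x$k_range)
  print(round(tab, 4))
  invisible(x)
}

#' Slope and intercept of an exponent-versus-scale curve
#'
#' Ordinary least squares of the curve value against k (in integer
#' multiples of the base bin width). Missing points are skipped; fewer
#' than two non-missing points yield missing features.
#'
#' @param curve a data frame with columns `k` and `value` (one entry of
#'   the `curves` list of [exponent_curves()]).
#' @return Named numeric vector `c(a = slope, b = intercept)`.
#' @export
fit_scale_line <- function(curve) {
  stopifnot(is.data.frame(curve), all(c("k", "value") %in% names(curve)))
  ok <- is.finite(curve$value)
  if (sum(ok) < 2L) return(c(a = NA_real_, b = NA_real_))
  cf <- stats::lsfit(curve$k[ok], curve$value[ok])$coefficients
  c(a = unname(cf[2L]), b = unname(cf[1L]))
}

#' Slope and intercept of one parameter curve against another
#'
#' Least squares of `y(k)` against `x(k)` over the scales where both
#' curves are non-missing; the x parameter (first in the canonical
#' sigma, alpha, tau, gamma, delta order) is the abscissa.
#'
#' @param x_curve,y_curve data frames with columns `k` and `value`.
#' @return Named numeric vector `c(a = slope, b = intercept)`.
#' @export
fit_pair_line <- function(x_curve, y_curve) {
  stopifnot(is.data.frame(x_curve), is.data.frame(y_curve))
  m <- merge(x_curve, y_curve, by = "k", suffixes = c("_x", "_y"))
  ok <- is.finite(m$value_x) & is.finite(m$value_y)
  if (sum(ok) < 2L || length(unique(m$value_x[ok])) < 2L)
    return(c(a = NA_real_, b = NA_real_))
  cf <- stats::lsfit(m$value_x[ok], m$value_y[ok])$coefficients
  c(a = unname(cf[2L]), b = unname(cf[1L]))
}

#' Multiscale criticality (MsCr) fingerprint of a recording
#'
#' Decimates the recording to the base rate, computes the exponent
#' profiles over all scales needed by the requested intervals, and
#' condenses each interval into the canonical 33-element feature vector:
#' slope/intercept of each parameter's scale curve (10), slope/intercept
#' of each parameter-pair curve (20), and kappa, generalized kappa and
#' size-distribution cutoff taken from the interval's smallest scale (3).
#'
#' @param rec an [recording()] object.
#' @param modality `"eeg"` or `"meg"`; selects the default threshold
#'   grid (2.5/3.0/3.5 std for EEG, 3.0/3.5/4.0 for MEG).
#' @param thresholds explicit threshold grid overriding `modality`.
#' @param intervals list of scale intervals, each `c(first k, last k)`;
#'   default the three canonical intervals 1-5, 3-7 and 6-10.
#' @param base_rate base sampling rate in Hz the recording is decimated
#'   to before analysis (default 250; skipped when already at or below).
#' @param config a [profile_config()].
#' @param recording_id identifier written into the output table.
#' @return A data frame of class `mscr_fingerprint`, one row per
#'   interval: `recording_id`, `interval`, then the 33 features in
#'   canonical order. Missing features are `NA`, never dropped. The
#'   underlying `mscr_curves` object is attached as attribute `curves`.
#' @examples
#' \donttest{
#' sim <- simulate_branching_raster(
#'   branching_config(n_channels = 16, n_bins = 20000, seed = 1))
#' rec <- render_continuous(sim$raster, sim$config)
#' fp <- mscr_fingerprint(rec, modality = "eeg")
#' fp$a_sigma
#' }
#' @export
mscr_fingerprint <- function(rec, modality = c("eeg", "meg"),
                             thresholds = NULL,
                             intervals = list(c(1, 5), c(3, 7), c(6, 10)),
                             base_rate = 250,
                             config = profile_config(),
                             recording_id = "rec") {
  stopifnot(inherits(rec, "mscr_recording"))
  modality <- match.arg(modality)
  if (is.null(thresholds))
    thresholds <- if (modality == "eeg") c(2.5, 3.0, 3.5) else c(3.0, 3.5, 4.0)
  if (rec$sampling_rate > base_rate)
    rec <- decimate_recording(rec, base_rate)
  ks <- sort(unique(unlist(lapply(intervals, function(iv) iv[1]:iv[2]))))
  cv <- exponent_curves(rec, thresholds, k_range = ks, config = config)
  rows <- lapply(intervals, function(iv) {
    fingerprint_row(cv, iv[1]:iv[2])
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- mscr_feature_names()
  out <- cbind(
    data.frame(recording_id = recording_id,
               interval = vapply(intervals, function(iv)
                 paste0(iv[1], "-", iv[2]), character(1))),
    out)
  attr(out, "curves") <- cv
  class(out) <- c("mscr_fingerprint", "data.frame")
  out
}

# 33-vector for one scale interval, from precomputed curves
fingerprint_row <- function(cv, ks) {
  sub <- lapply(cv$curves, function(d) d[d$k %in% ks, , drop = FALSE])
  singles <- unlist(lapply(MSCR_PARAMS, function(p) fit_scale_line(sub[[p]])))
  prs <- utils::combn(MSCR_PARAMS, 2)
  pairs <- unlist(lapply(seq_len(ncol(prs)), function(j)
    fit_pair_line(sub[[prs[1, j]]], sub[[prs[2, j]]])))
  k0 <- paste0("k", min(ks))
  prof <- cv$profiles[[k0]]
  tail3 <- if (is.null(prof)) rep(NA_real_, 3)
           else c(prof$kappa, prof$kappa_gen, prof$cutoff)
  out <- c(singles, pairs, tail3)
  names(out) <- mscr_feature_names()
  out
}

#' Write / read MsCr fingerprint tables
#'
#' Fingerprints are exchanged as a tab-delimited table, one row per
#' recording x interval, with the 33 canonical feature columns. This is
#' the interchange surface for the group-comparison statistics.
#'
#' @param fp a fingerprint data frame (rows from [mscr_fingerprint()],
#'   possibly concatenated across recordings).
#' @param path file path.
#' @return `write_fingerprints()` returns `path` invisibly;
#'   `read_fingerprints()` returns the data frame.
#' @export
write_fingerprints <- function(fp, path) {
  utils::write.table(as.data.frame(fp), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fingerprints
#' @export
read_fingerprints <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(mscr_feature_names(), names(out))
  if (length(miss))
    stop("fingerprint table lacks canonical features: ",
         paste(miss, collapse = ", "))
  out
}
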