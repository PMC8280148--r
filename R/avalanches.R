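#' Extract neuronal avalanches from an event raster
#'
#' An avalanche is a maximal run of consecutive time bins each containing
#' at least one event on any channel, bounded by empty bins or the record
#' edges. Its size is the total number of base-interval events (summed
#' over channels and bins of the run, from the raster's `base_counts`),
#' its duration the number of bins in the run, and the inter-avalanche
#' interval (IAI) the number of empty bins between the end of one
#' avalanche and the start of the next.
#'
#' @param raster an [event_raster()] at any scale.
#' @return An object of class `avalanche_set`: a list with `sizes`,
#'   `durations`, `iai`, `bin_profiles` (per-avalanche vector of per-bin
#'   base-event counts), `start_bin`, `scale_k`, `threshold`,
#'   `n_channels`, `n_bins`, `total_events`. A raster with no events
#'   yields an empty set, not an error.
#' @examples
#' rec <- recording(matrix(rnorm(2000), nrow = 4), sampling_rate = 250)
#' av <- extract_avalanches(detect_events(rec, 2.5))
#' length(av$sizes)
#' @export
extract_avalanches <- function(raster) {
  stopifnot(inherits(raster, "event_raster"))
  bc <- raster$base_counts
  occ <- bc > 0L
  n_bins <- length(bc)
  if (!any(occ)) {
    return(new_avalanche_set(integer(0), integer(0), integer(0), list(),
                             integer(0), raster, n_bins))
  }
  r <- rle(occ)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  a_start <- starts[idx]
  a_len <- r$lengths[idx]
  a_end <- ends[idx]
  cs <- c(0L, cumsum(bc))
  sizes <- cs[a_end + 1L] - cs[a_start]
  profiles <- mapply(function(s, e) bc[s:e], a_start, a_end,
                     SIMPLIFY = FALSE)
  n_av <- length(a_start)
  iai <- if (n_av > 1L) a_start[-1L] - a_end[-n_av] - 1L else integer(0)
  new_avalanche_set(as.integer(sizes), as.integer(a_len), as.integer(iai),
                    profiles, as.integer(a_start), raster, n_bins)
}

new_avalanche_set <- function(sizes, durations, iai, profiles, start_bin,
                              raster, n_bins) {
  structure(
    list(sizes = sizes, durations = durations, iai = iai,
         bin_profiles = profiles, start_bin = start_bin,
         scale_k = raster$k, threshold = raster$threshold,
         n_channels = nrow(raster$events), n_bins = n_bins,
         total_events = sum(raster$base_counts)),
    class = "avalanche_set")
}

#' @export
print.avalanche_set <- function(x, ...) {
  cat(sprintf(
    "<avalanche_set> %d avalanches (k = %d, threshold = %s, %d channels)\n",
    length(x$sizes), x$scale_k,
    if (is.na(x$threshold)) "NA" else format(x$threshold), x$n_channels))
  if (length(x$sizes))
    cat(sprintf("  size: median %g max %g | duration: median %g max %g\n",
                stats::median(x$sizes), max(x$sizes),
                stats::median(x$durations), max(x$durations)))
  invisible(x)
}

#' Pool avalanche sets
#'
#' Concatenates the avalanches of several sets (e.g. one per detection
#' threshold at a common scale), implementing count-weighted averaging of
#' the empirical distributions: fitting the pooled sample weighs each
#' set by its avalanche count. IAIs are concatenated within sets only;
#' no interval is formed across set boundaries.
#'
#' @param sets a list of `avalanche_set` objects at a common scale.
#' @return A single `avalanche_set` with `threshold = NA`.
#' @export
pool_avalanches <- function(sets) {
  stopifnot(length(sets) >= 1L,
            all(vapply(sets, inherits, logical(1), "avalanche_set")))
  k <- unique(vapply(sets, `[[`, integer(1), "scale_k"))
  if (length(k) != 1L) stop("cannot pool avalanche sets at different scales")
  out <- sets[[1L]]
  out$sizes <- unlist(lapply(sets, `[[`, "sizes"), use.names = FALSE)
  out$durations <- unlist(lapply(sets, `[[`, "durations"), use.names = FALSE)
  out$iai <- unlist(lapply(sets, `[[`, "iai"), use.names = FALSE)
  out$bin_profiles <- do.call(c, lapply(sets, `[[`, "bin_profiles"))
  out$start_bin <- unlist(lapply(sets, `[[`, "start_bin"), use.names = FALSE)
  out$threshold <- NA_real_
  out$total_events <- sum(vapply(sets, `[[`, numeric(1), "total_events"))
  out
}

#' Branching parameter of an avalanche set
#'
#' The branching parameter sigma is the mean over avalanches of the ratio
#' of base events in the second bin to base events in the first bin. By
#' default, duration-1 avalanches contribute a ratio of 0 (they have no
#' second bin: the cascade produced no descendants), which makes the
#' estimator unbiased for a branching process with Poisson offspring.
#' Setting `include_singletons = FALSE` averages only over avalanches of
#' duration >= 2; note that this conditions on a non-empty second bin and
#' biases the estimate upward when first bins hold few events.
#'
#' @param av an `avalanche_set`.
#' @param include_singletons count duration-1 avalanches as ratio 0?
#' @return Sigma (dimensionless), or `NA` (with a `reason` attribute) if
#'   no qualifying avalanche exists.
#' @export
branching_parameter <- function(av, include_singletons = TRUE) {
  stopifnot(inherits(av, "avalanche_set"))
  if (!length(av$sizes))
    return(structure(NA_real_, reason = "no avalanches"))
  n1 <- vapply(av$bin_profiles, `[[`, numeric(1), 1L)
  n2 <- vapply(av$bin_profiles,
               function(p) if (length(p) >= 2L) p[[2L]] else 0, numeric(1))
  if (!include_singletons) {
    keep <- av$durations >= 2L
    if (!any(keep))
      return(structure(NA_real_, reason = "no avalanche of duration >= 2"))
    n1 <- n1[keep]; n2 <- n2[keep]
  }
  mean(n2 / n1)
}

#' Tidy table of avalanches
#'
#' @param av an `avalanche_set`.
#' @return A data frame with columns `avalanche_id`, `size`, `duration`,
#'   `start_bin`. The IAI sequence is attached as attribute `iai`.
#' @export
avalanche_table <- function(av) {
  stopifnot(inherits(av, "avalanche_set"))
  out <- data.frame(avalanche_id = seq_along(av$sizes),
                    size = av$sizes, duration = av$durations,
                    start_bin = av$start_bin)
  attr(out, "iai") <- av$iai
  out
}
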