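#' Configuration of the branching-process generator
#'
#' Describes a critical/sub/supercritical cascade process on a sensor
#' array: each active event spawns a Poisson(`branching_ratio`) number of
#' descendant events in the next time bin, assigned to uniformly random
#' channels; fresh cascades are seeded by a Poisson(`drive_rate`) count
#' of spontaneous events per bin. `noise_std` and `pulse_amplitude`
#' (both in units of the sensor noise standard deviation) govern the
#' continuous rendering of the raster.
#'
#' @param n_channels number of channels (>= 2).
#' @param n_bins number of time bins.
#' @param branching_ratio expected descendants per event (>= 0); 1 is
#'   critical.
#' @param drive_rate expected spontaneous seed events per bin (> 0).
#' @param noise_std additive Gaussian sensor noise standard deviation.
#' @param pulse_amplitude event pulse amplitude; must clear the intended
#'   detection threshold (`pulse_amplitude > threshold + 2 * noise_std`
#'   for near-certain recovery).
#' @param dt bin width in seconds (default 0.004, i.e. 250 Hz).
#' @param max_active runaway guard: a cascade whose offspring count
#'   exceeds this is truncated and flagged. Default `100 * n_channels`.
#' @param seed integer RNG seed, or `NULL` to use the current RNG state.
#' @return A list of class `branching_config`.
#' @export
branching_config <- function(n_channels = 64, n_bins = 1e5,
                             branching_ratio = 1.0, drive_rate = 0.02,
                             noise_std = 1, pulse_amplitude = 8,
                             dt = 0.004, max_active = 100 * n_channels,
                             seed = NULL) {
  if (n_channels < 2) stop("'n_channels' must be >= 2")
  if (drive_rate <= 0) stop("'drive_rate' must be > 0")
  if (branching_ratio < 0) stop("'branching_ratio' must be >= 0")
  if (n_bins < 1) stop("'n_bins' must be >= 1")
  structure(list(n_channels = as.integer(n_channels),
                 n_bins = as.integer(n_bins),
                 branching_ratio = branching_ratio,
                 drive_rate = drive_rate, noise_std = noise_std,
                 pulse_amplitude = pulse_amplitude, dt = dt,
                 max_active = max_active, seed = seed),
            class = "branching_config")
}

#' Sample from a truncated discrete power law
#'
#' I.i.d. draws from `P(x) proportional to x^(-exponent) * exp(-x/cutoff)`
#' on the integer support `[xmin, xmax]` by inverse-CDF lookup on the
#' exact normalized mass function. The default `cutoff = Inf` gives the
#' pure truncated power law.
#'
#' @param n number of draws.
#' @param exponent power-law exponent (>= 0).
#' @param xmin,xmax integer support, `xmax >= xmin >= 1`.
#' @param seed integer RNG seed, or `NULL`.
#' @param cutoff exponential drop-off scale (default `Inf`: none).
#' @return Integer vector of length `n`.
#' @examples
#' table(sample_discrete_powerlaw(1000, 1.5, 1, 4, seed = 1))
#' @export
sample_discrete_powerlaw <- function(n, exponent, xmin, xmax, seed = NULL,
                                     cutoff = Inf) {
  check_support(xmin, xmax)
  if (exponent < 0) stop("'exponent' must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  xs <- xmin:xmax
  if (xmin == xmax) return(rep.int(as.integer(xmin), n))
  w <- xs^(-exponent) * exp(-xs / cutoff)
  cum <- cumsum(w) / sum(w)
  xs[findInterval(stats::runif(n), cum) + 1L]
}

#' Simulate a branching-process event raster
#'
#' Runs the cascade process of [branching_config()]: per bin, every
#' active event spawns a Poisson(`branching_ratio`) number of descendants
#' in the next bin on uniformly random channels; fresh cascades arrive as
#' Poisson(`drive_rate`) seeds per bin. Events landing on the same
#' channel-bin merge in the binary raster but are all retained in the
#' raster's `base_counts`, so avalanche sizes count every event.
#'
#' @param cfg a [branching_config()].
#' @return A list of class `branching_sim`: `raster` (an
#'   [event_raster()] with `threshold = NA`), `cascades` (data frame of
#'   ground-truth annotations: `cascade_id`, `start_bin`, `size`,
#'   `duration`, `truncated`), and `config`. Cascades still active at the
#'   record end are annotated with their within-record size/duration.
#' @examples
#' sim <- simulate_branching_raster(
#'   branching_config(n_channels = 8, n_bins = 2000, seed = 1))
#' nrow(sim$cascades)
#' @export
simulate_branching_raster <- function(cfg) {
  stopifnot(inherits(cfg, "branching_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  nch <- cfg$n_channels; nbins <- cfg$n_bins
  ratio <- cfg$branching_ratio; drive <- cfg$drive_rate
  p_seed <- 1 - exp(-drive)

  cap <- 1024L; hit_ch <- integer(cap); hit_bin <- integer(cap); nh <- 0L
  base_counts <- integer(nbins)
  cid_next <- 1L
  act_id <- integer(0); act_n <- numeric(0)
  cs_cap <- 1024L
  cs_size <- integer(cs_cap); cs_dur <- integer(cs_cap)
  cs_start <- integer(cs_cap); cs_trunc <- logical(cs_cap)

  t <- 1L
  while (t <= nbins) {
    if (length(act_id) == 0L) {
      # nothing active: jump the quiet gap to the next seeded bin
      t <- t + stats::rgeom(1L, p_seed)
      if (t > nbins || is.na(t)) break
      ns <- stats::qpois(stats::runif(1, stats::ppois(0, drive), 1), drive)
    } else {
      ns <- stats::rpois(1L, drive)
    }
    if (ns > 0L) {
      ids <- cid_next:(cid_next + ns - 1L)
      cid_next <- cid_next + ns
      act_id <- c(act_id, ids); act_n <- c(act_n, rep(1, ns))
      while (cid_next - 1L > cs_cap) {
        cs_cap <- cs_cap * 2L
        length(cs_size) <- cs_cap; length(cs_dur) <- cs_cap
        length(cs_start) <- cs_cap; length(cs_trunc) <- cs_cap
      }
      cs_start[ids] <- t
      cs_size[ids] <- 0L; cs_dur[ids] <- 0L; cs_trunc[ids] <- FALSE
    }
    tot <- sum(act_n)
    if (tot > 0) {
      ch <- unique(sample.int(nch, tot, replace = TRUE))
      nk <- length(ch)
      if (nh + nk > cap) {
        cap <- max(cap * 2L, nh + nk)
        length(hit_ch) <- cap; length(hit_bin) <- cap
      }
      hit_ch[(nh + 1L):(nh + nk)] <- ch
      hit_bin[(nh + 1L):(nh + nk)] <- t
      nh <- nh + nk
      base_counts[t] <- as.integer(tot)
      cs_size[act_id] <- cs_size[act_id] + as.integer(act_n)
      cs_dur[act_id] <- cs_dur[act_id] + 1L
      off <- stats::rpois(length(act_n), ratio * act_n)
      over <- off > cfg$max_active
      if (any(over)) {
        cs_trunc[act_id[over]] <- TRUE
        off[over] <- 0L
      }
      keep <- off > 0L
      act_id <- act_id[keep]; act_n <- off[keep]
    }
    t <- t + 1L
  }

  n_casc <- cid_next - 1L
  cascades <- data.frame(
    cascade_id = seq_len(n_casc),
    start_bin = cs_start[seq_len(n_casc)],
    size = cs_size[seq_len(n_casc)],
    duration = cs_dur[seq_len(n_casc)],
    truncated = cs_trunc[seq_len(n_casc)])
  events <- Matrix::sparseMatrix(i = hit_ch[seq_len(nh)],
                                 j = hit_bin[seq_len(nh)], x = 1,
                                 dims = c(nch, nbins))
  raster <- event_raster(events, base_counts, base_dt = cfg$dt, k = 1L,
                         threshold = NA_real_)
  structure(list(raster = raster, cascades = cascades, config = cfg),
            class = "branching_sim")
}

#' @export
print.branching_sim <- function(x, ...) {
  cat(sprintf(
    "<branching_sim> ratio %.2f, %d channels x %d bins: %d cascades, %d events\n",
    x$config$branching_ratio, x$config$n_channels, x$config$n_bins,
    nrow(x$cascades), sum(x$raster$base_counts)))
  invisible(x)
}

#' Render an event raster as a continuous noisy recording
#'
#' Each occupied channel-bin becomes a brief biphasic pulse (a 3-sample
#' kernel `amplitude * c(-0.3, 1, -0.3)`, centered on the event sample)
#' on top of additive Gaussian noise, one sample per bin. Standardized
#' thresholding by [detect_events()] recovers the planted events.
#'
#' @param raster an [event_raster()] at the base bin width.
#' @param cfg a [branching_config()] supplying `noise_std`,
#'   `pulse_amplitude` and `dt`.
#' @param seed RNG seed for the noise, or `NULL` (default: `cfg$seed`
#'   advanced by one, so raster and rendering draws decouple).
#' @return An [recording()] at `1 / cfg$dt` Hz.
#' @export
render_continuous <- function(raster, cfg, seed = NULL) {
  stopifnot(inherits(raster, "event_raster"),
            inherits(cfg, "branching_config"))
  if (raster$k != 1L) stop("'raster' must be at the base bin width")
  if (is.null(seed) && !is.null(cfg$seed)) seed <- cfg$seed + 1L
  if (!is.null(seed)) set.seed(seed)
  nch <- nrow(raster$events); nbins <- ncol(raster$events)
  data <- matrix(stats::rnorm(nch * nbins, sd = cfg$noise_std),
                 nrow = nch)
  if (cfg$pulse_amplitude != 0 && length(raster$events@x)) {
    kernel <- cfg$pulse_amplitude * c(-0.3, 1, -0.3)
    tr <- Matrix::summary(raster$events)  # i = channel, j = bin
    for (off in -1:1) {
      j <- tr$j + off
      ok <- j >= 1L & j <= nbins
      idx <- (j[ok] - 1L) * nch + tr$i[ok]
      kv <- kernel[off + 2L]
      # side lobes of events in adjacent bins can land on one sample
      agg <- rowsum(rep(kv, length(idx)), idx)
      ui <- as.integer(rownames(agg))
      data[ui] <- data[ui] + agg[, 1L]
    }
  }
  recording(data, sampling_rate = 1 / cfg$dt,
            channel_labels = raster$channel_labels)
}
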