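#' Truncated discrete power-law distribution
#'
#' Probability mass and cumulative distribution of
#' `P(x) = x^(-exponent) / Z` on the integer support `xmin:xmax`,
#' with `Z = sum(x^-exponent)` over the support. Any real exponent is
#' allowed (exponent 0 is the discrete uniform).
#'
#' @param x,q integer values at which to evaluate (for the CDF, `q` may
#'   be any real; mass at integers `<= q` is accumulated).
#' @param exponent power-law exponent.
#' @param xmin,xmax integer support bounds, `1 <= xmin < xmax` (equal
#'   bounds allowed for the degenerate point mass).
#' @return Numeric vector of probabilities.
#' @export
powerlaw_pmf <- function(x, exponent, xmin, xmax) {
  check_support(xmin, xmax)
  xs <- xmin:xmax
  z <- sum(xs^(-exponent))
  out <- numeric(length(x))
  ok <- x >= xmin & x <= xmax & x == floor(x)
  out[ok] <- x[ok]^(-exponent) / z
  out
}

#' @rdname powerlaw_pmf
#' @export
powerlaw_cdf <- function(q, exponent, xmin, xmax) {
  check_support(xmin, xmax)
  xs <- xmin:xmax
  p <- xs^(-exponent)
  cum <- cumsum(p) / sum(p)
  idx <- pmin(pmax(floor(q) - xmin + 1, 0), length(xs))
  c(0, cum)[idx + 1]
}

check_support <- function(xmin, xmax) {
  if (xmin < 1 || xmax < xmin || xmin != floor(xmin) || xmax != floor(xmax))
    stop("invalid support: need integer 1 <= xmin <= xmax")
  invisible(TRUE)
}

#' Truncated discrete power-law fit by maximum likelihood
#'
#' Fits the exponent of `P(x) proportional to x^(-e)` on the integer
#' support `[xmin, xmax]` by one-dimensional numerical maximization of
#' the exact truncated likelihood. Samples outside the support are
#' discarded before fitting.
#'
#' @param samples positive integer observations.
#' @param xmin,xmax integer support bounds.
#' @param min_n minimum number of in-range samples required (default 50);
#'   with fewer the fit is refused and `NA` returned.
#' @param interval search interval for the exponent.
#' @return A list of class `powerlaw_fit`: `exponent` (`NA` on failure),
#'   `n` (in-range sample count), `xmin`, `xmax`, `reason` (why the fit
#'   is missing, or `NA`).
#' @examples
#' x <- sample_discrete_powerlaw(5000, 1.5, 1, 100, seed = 1)
#' fit_discrete_powerlaw_mle(x, 1, 100)$exponent
#' @export
fit_discrete_powerlaw_mle <- function(samples, xmin, xmax, min_n = 50,
                                      interval = c(-5, 25)) {
  check_support(xmin, xmax)
  x <- samples[samples >= xmin & samples <= xmax]
  n <- length(x)
  fail <- function(reason)
    structure(list(exponent = NA_real_, n = n, xmin = xmin, xmax = xmax,
                   reason = reason), class = "powerlaw_fit")
  if (n < min_n) return(fail(sprintf("only %d samples in [%d, %d] (< %d)",
                                     n, xmin, xmax, min_n)))
  if (all(x == x[1L]) && xmin < xmax)
    return(fail("all in-range samples identical: exponent diverges"))
  S <- sum(log(x))
  xs <- xmin:xmax
  lxs <- -log(xs)
  nll <- function(e) e * S + n * log(sum(exp(e * lxs)))
  opt <- stats::optimize(nll, interval = interval, tol = 1e-7)
  structure(list(exponent = opt$minimum, n = n, xmin = xmin, xmax = xmax,
                 reason = NA_character_), class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  if (is.na(x$exponent))
    cat(sprintf("<powerlaw_fit> missing (%s)\n", x$reason))
  else
    cat(sprintf("<powerlaw_fit> exponent %.4f on [%d, %d], n = %d\n",
                x$exponent, x$xmin, x$xmax, x$n))
  invisible(x)
}

#' Mean-size-per-duration scaling exponent
#'
#' Gamma is the slope of the least-squares line of `log(mean size)`
#' against `log(duration)`, over durations represented by at least
#' `min_per_duration` avalanches. At least `min_durations` distinct
#' qualifying durations are required.
#'
#' @param av an `avalanche_set`.
#' @param min_per_duration minimum avalanches per duration (default 5).
#' @param min_durations minimum distinct qualifying durations (default 3).
#' @return Gamma, or `NA` with a `reason` attribute.
#' @export
fit_gamma <- function(av, min_per_duration = 5, min_durations = 3) {
  stopifnot(inherits(av, "avalanche_set"))
  if (!length(av$sizes))
    return(structure(NA_real_, reason = "no avalanches"))
  counts <- table(av$durations)
  ok <- counts >= min_per_duration
  if (sum(ok) < min_durations)
    return(structure(NA_real_,
      reason = sprintf("%d qualifying durations (< %d)", sum(ok), min_durations)))
  durs <- as.numeric(names(counts)[ok])
  means <- vapply(durs, function(d) mean(av$sizes[av$durations == d]),
                  numeric(1))
  unname(stats::lsfit(log(durs), log(means))$coefficients[2L])
}

#' Kappa: deviance from a reference power law
#'
#' Kappa is 1 plus the mean difference between the reference truncated
#' discrete power-law CDF and the empirical CDF, evaluated at `m`
#' logarithmically spaced probe points in `[xmin, xmax]`. Kappa of 1
#' indicates agreement with the reference; above 1, an excess of large
#' events (supercritical); below 1, a deficit (subcritical).
#'
#' `generalized_kappa()` uses the sample's own maximum-likelihood
#' exponent as the reference, so it isolates deviance of distributional
#' *shape* from the particular exponent value: an exact power-law sample
#' at any exponent scores near 1.
#'
#' @param sizes positive integer observations.
#' @param reference_exponent exponent of the reference power law
#'   (default 1.5, the mean-field critical value for avalanche sizes).
#' @param xmin,xmax integer support bounds of the comparison.
#' @param m number of logarithmically spaced probe points (>= 2).
#' @param min_n minimum in-range samples for the MLE step of
#'   `generalized_kappa()`.
#' @return Kappa (dimensionless), or `NA` with a `reason` attribute.
#' @examples
#' x <- sample_discrete_powerlaw(5000, 1.5, 1, 64, seed = 1)
#' kappa_powerlaw(x, 1.5, 1, 64)
#' @export
kappa_powerlaw <- function(sizes, reference_exponent = 1.5, xmin = 1,
                           xmax = max(sizes), m = 10) {
  check_support(xmin, xmax)
  if (m < 2) stop("'m' must be >= 2")
  x <- sizes[sizes >= xmin & sizes <= xmax]
  if (!length(x))
    return(structure(NA_real_, reason = "no samples in support"))
  beta <- exp(seq(log(xmin), log(xmax), length.out = m))
  f_ref <- powerlaw_cdf(beta, reference_exponent, xmin, xmax)
  f_emp <- stats::ecdf(x)(floor(beta))
  1 + mean(f_ref - f_emp)
}

#' @rdname kappa_powerlaw
#' @export
generalized_kappa <- function(sizes, xmin = 1, xmax = max(sizes), m = 10,
                              min_n = 50) {
  fit <- fit_discrete_powerlaw_mle(sizes, xmin, xmax, min_n = min_n)
  if (is.na(fit$exponent))
    return(structure(NA_real_, reason = fit$reason))
  kappa_powerlaw(sizes, reference_exponent = fit$exponent,
                 xmin = xmin, xmax = xmax, m = m)
}

#' Distribution drop-off scale
#'
#' Fits a discrete power law with exponential tail,
#' `P(x) proportional to x^(-e) * exp(-x / s_c)` on the observed support
#' `[xmin, max(x)]`, by joint two-parameter maximum likelihood, and
#' returns the drop-off scale `s_c`. Bounding the model support by the
#' observed maximum mirrors the truncated supports used for the plain
#' power-law fits; for a sample with no interior drop-off (a pure power
#' law) the estimate then runs to the upper optimization bound, which
#' exceeds the sample maximum.
#'
#' @param sizes positive integer observations.
#' @param xmin lower support bound (default 1).
#' @param min_n minimum sample count (default 50).
#' @param s_max upper bound of the drop-off scale search (default 1e6).
#' @return A list of class `cutoff_fit`: `cutoff` (`s_c`), `exponent`,
#'   `n`, `reason`.
#' @export
distribution_cutoff <- function(sizes, xmin = 1, min_n = 50, s_max = 1e6) {
  x <- sizes[sizes >= xmin]
  n <- length(x)
  fail <- function(reason)
    structure(list(cutoff = NA_real_, exponent = NA_real_, n = n,
                   reason = reason), class = "cutoff_fit")
  if (n < min_n) return(fail(sprintf("only %d samples >= %d (< %d)",
                                     n, xmin, min_n)))
  if (all(x == xmin)) return(fail("all samples at xmin: no tail information"))
  # normalization over the observed support. The head is summed exactly;
  # the (smooth, slowly varying) tail beyond x_head is approximated by
  # the midpoint-rule integral.
  x_hi <- max(x)
  x_head <- min(x_hi, 5000)
  xs <- xmin:x_head
  lxs <- log(xs)
  S <- sum(log(x)); Tx <- sum(x)
  nll <- function(par) {
    e <- par[1L]; s <- exp(par[2L])
    z <- sum(exp(-e * lxs - xs / s))
    if (x_hi > x_head)
      z <- z + stats::integrate(function(u) u^(-e) * exp(-u / s),
                                x_head + 0.5, x_hi + 0.5,
                                rel.tol = 1e-9)$value
    e * S + Tx / s + n * log(z)
  }
  opt <- try(stats::optim(c(1.5, log(x_hi)), nll, method = "L-BFGS-B",
                          lower = c(-5, log(max(xmin, 1))),
                          upper = c(25, log(s_max))), silent = TRUE)
  if (inherits(opt, "try-error") || opt$convergence != 0)
    return(fail("optimizer failed to converge"))
  structure(list(cutoff = exp(opt$par[2L]), exponent = opt$par[1L], n = n,
                 reason = NA_character_), class = "cutoff_fit")
}

#' @export
print.cutoff_fit <- function(x, ...) {
  if (is.na(x$cutoff))
    cat(sprintf("<cutoff_fit> missing (%s)\n", x$reason))
  else
    cat(sprintf("<cutoff_fit> s_c = %.3g, exponent = %.3f, n = %d\n",
                x$cutoff, x$exponent, x$n))
  invisible(x)
}

#' Fit configuration for exponent profiles
#'
#' Collects the tunable supports and floors of the per-scale fits.
#' `size_xmax = NULL` caps avalanche-size fits at
#' `n_channels * scale_k` (one event per channel per base bin is the
#' nominal ceiling of the scaling regime); duration and IAI fits default
#' to the full observed range with floor 1.
#'
#' @param size_xmin,size_xmax support for the size exponent alpha.
#' @param dur_xmin,dur_xmax support for the duration exponent tau
#'   (`NULL` xmax: observed maximum).
#' @param iai_xmin,iai_xmax support for the inter-avalanche-interval
#'   exponent delta (`NULL` xmax: observed maximum).
#' @param kappa_exponent reference exponent for kappa (default 1.5).
#' @param kappa_m number of kappa probe points.
#' @param min_samples minimum in-range sample count for any MLE fit.
#' @param min_per_duration,min_durations floors for the gamma regression.
#' @param sigma_include_singletons passed to [branching_parameter()].
#' @return A list of class `profile_config`.
#' @export
profile_config <- function(size_xmin = 1, size_xmax = NULL,
                           dur_xmin = 1, dur_xmax = NULL,
                           iai_xmin = 1, iai_xmax = NULL,
                           kappa_exponent = 1.5, kappa_m = 10,
                           min_samples = 50,
                           min_per_duration = 5, min_durations = 3,
                           sigma_include_singletons = TRUE) {
  structure(as.list(environment()), class = "profile_config")
}

#' Criticality exponent profile at one temporal scale
#'
#' Assembles the five criticality parameters (sigma, alpha, tau, gamma,
#' delta) plus kappa, generalized kappa and the size-distribution
#' drop-off for one avalanche set. Components that cannot be computed
#' (insufficient data) are `NA` and listed in `flags`, never silently
#' zero.
#'
#' @param av an `avalanche_set` (typically threshold-pooled).
#' @param config a [profile_config()].
#' @return An object of class `exponent_profile`: a list with the eight
#'   measures, `scale_k`, and a character vector `flags` naming missing
#'   components with reasons.
#' @export
profile_at_scale <- function(av, config = profile_config()) {
  stopifnot(inherits(av, "avalanche_set"),
            inherits(config, "profile_config"))
  flags <- character(0)
  note <- function(name, reason) {
    flags[[name]] <<- if (is.null(reason)) "missing" else reason
    NA_real_
  }
  get_reason <- function(x) {
    r <- attr(x, "reason")
    if (is.null(r)) "insufficient data" else r
  }
  empty <- length(av$sizes) == 0L

  sigma <- if (empty) note("sigma", "no avalanches") else {
    s <- branching_parameter(av, config$sigma_include_singletons)
    if (is.na(s)) note("sigma", get_reason(s)) else as.numeric(s)
  }

  size_xmax <- if (is.null(config$size_xmax)) av$n_channels * av$scale_k
               else config$size_xmax
  alpha <- tau <- delta <- NA_real_
  kap <- kap_gen <- cutoff <- NA_real_
  if (empty) {
    for (nm in c("alpha", "tau", "delta", "kappa", "kappa_gen", "cutoff"))
      note(nm, "no avalanches")
  } else {
    f <- fit_discrete_powerlaw_mle(av$sizes, config$size_xmin, size_xmax,
                                   min_n = config$min_samples)
    alpha <- if (is.na(f$exponent)) note("alpha", f$reason) else f$exponent

    dmax <- if (is.null(config$dur_xmax)) max(av$durations) else config$dur_xmax
    tau <- if (dmax <= config$dur_xmin)
      note("tau", "degenerate duration range")
    else {
      f <- fit_discrete_powerlaw_mle(av$durations, config$dur_xmin, dmax,
                                     min_n = config$min_samples)
      if (is.na(f$exponent)) note("tau", f$reason) else f$exponent
    }

    delta <- if (!length(av$iai)) note("delta", "no intervals") else {
      imax <- if (is.null(config$iai_xmax)) max(av$iai) else config$iai_xmax
      if (imax <= config$iai_xmin) note("delta", "degenerate interval range")
      else {
        f <- fit_discrete_powerlaw_mle(av$iai, config$iai_xmin, imax,
                                       min_n = config$min_samples)
        if (is.na(f$exponent)) note("delta", f$reason) else f$exponent
      }
    }

    kap <- kappa_powerlaw(av$sizes, config$kappa_exponent,
                          config$size_xmin, size_xmax, m = config$kappa_m)
    if (is.na(kap)) kap <- note("kappa", get_reason(kap))
    kap_gen <- generalized_kappa(av$sizes, config$size_xmin, size_xmax,
                                 m = config$kappa_m,
                                 min_n = config$min_samples)
    if (is.na(kap_gen)) kap_gen <- note("kappa_gen", get_reason(kap_gen))
    cf <- distribution_cutoff(av$sizes, config$size_xmin,
                              min_n = config$min_samples)
    cutoff <- if (is.na(cf$cutoff)) note("cutoff", cf$reason) else cf$cutoff
  }

  gamma <- if (empty) note("gamma", "no avalanches") else {
    g <- fit_gamma(av, config$min_per_duration, config$min_durations)
    if (is.na(g)) note("gamma", get_reason(g)) else as.numeric(g)
  }

  structure(
    list(sigma = sigma, alpha = alpha, tau = tau, gamma = gamma,
         delta = delta, kappa = kap, kappa_gen = kap_gen, cutoff = cutoff,
         scale_k = av$scale_k, flags = flags),
    class = "exponent_profile")
}

#' @export
print.exponent_profile <- function(x, ...) {
  cat(sprintf("<exponent_profile> k = %d\n", x$scale_k))
  v <- unlist(x[c("sigma", "alpha", "tau", "gamma", "delta",
                  "kappa", "kappa_gen", "cutoff")])
  print(round(v, 4))
  if (length(x$flags))
    cat("  missing:", paste(names(x$flags), collapse = ", "), "\n")
  invisible(x)
}
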