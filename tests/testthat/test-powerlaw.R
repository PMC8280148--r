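test_that("pmf/cdf are exactly normalized and match direct sums", {
  xs <- 1:100
  p <- powerlaw_pmf(xs, 1.5, 1, 100)
  expect_equal(sum(p), 1)
  expect_equal(p, xs^(-1.5) / sum(xs^(-1.5)))
  expect_equal(powerlaw_cdf(100, 1.5, 1, 100), 1)
  expect_equal(powerlaw_cdf(0.5, 1.5, 1, 100), 0)
  expect_equal(powerlaw_cdf(7.9, 1.5, 1, 100), sum(p[1:7]))
  expect_error(powerlaw_pmf(1, 1.5, 0, 10), "support")
})

test_that("MLE matches a brute-force likelihood grid, including tiny and flat samples", {
  # the 4-sample set {1,1,1,2} on [1,2]: exhaustive 0.001-step grid
  fit <- fit_discrete_powerlaw_mle(c(1, 1, 1, 2), 1, 2, min_n = 1)
  expect_equal(fit$exponent, grid_mle(c(1, 1, 1, 2), 1, 2), tolerance = 1e-3)
  # uniform draws (exponent 0 truth)
  x0 <- sample_discrete_powerlaw(1e5, 0, 1, 100, seed = 101)
  f0 <- fit_discrete_powerlaw_mle(x0, 1, 100)
  expect_lt(abs(f0$exponent - grid_mle(x0, 1, 100)), 2e-3)
  expect_lt(abs(f0$exponent), 0.05)
  # exponent 1.5 truth
  x1 <- sample_discrete_powerlaw(1e5, 1.5, 1, 100, seed = 102)
  f1 <- fit_discrete_powerlaw_mle(x1, 1, 100)
  expect_equal(f1$exponent, grid_mle(x1, 1, 100), tolerance = 2e-3)
  expect_lt(abs(f1$exponent - 1.5), 0.05)
})

test_that("MLE refusal paths: sample floor, identical samples, out-of-range discard", {
  f <- fit_discrete_powerlaw_mle(rep(2, 10), 1, 10)
  expect_true(is.na(f$exponent))
  expect_match(f$reason, "< 50")
  f2 <- fit_discrete_powerlaw_mle(rep(3, 100), 1, 10)
  expect_match(f2$reason, "identical")
  # out-of-range samples are discarded before fitting
  x <- sample_discrete_powerlaw(2e4, 1.5, 1, 50, seed = 103)
  xx <- c(x, rep(1000L, 500))
  expect_equal(fit_discrete_powerlaw_mle(xx, 1, 50)$exponent,
               fit_discrete_powerlaw_mle(x, 1, 50)$exponent)
})

test_that("MLE is equivariant under sample duplication and tightens with n", {
  x <- sample_discrete_powerlaw(2e3, 1.5, 1, 100, seed = 104)
  expect_equal(fit_discrete_powerlaw_mle(c(x, x), 1, 100)$exponent,
               fit_discrete_powerlaw_mle(x, 1, 100)$exponent, tolerance = 1e-6)
  # bias decreasing with n over a grid of true exponents
  for (e in c(1.2, 1.5, 2.0)) {
    err <- vapply(c(1e3, 1e4), function(n) {
      est <- vapply(1:10, function(s)
        fit_discrete_powerlaw_mle(
          sample_discrete_powerlaw(n, e, 1, 100, seed = 1000 * e + s),
          1, 100)$exponent, numeric(1))
      abs(mean(est) - e)
    }, numeric(1))
    expect_lt(err[2], 0.05)
    expect_lt(err[2], err[1] + 0.02)
  }
})

test_that("gamma regression: exact line, degenerate input, independent oracle", {
  mk_av <- function(durations, sizes) {
    counts <- unlist(mapply(function(d, s) {
      prof <- rep(s %/% d, d); prof[1] <- prof[1] + s %% d
      c(prof, 0L)
    }, durations, sizes, SIMPLIFY = FALSE))
    m <- matrix(0, 2, length(counts)); m[1, counts > 0] <- 1
    extract_avalanches(event_raster(m, counts, base_dt = 0.004))
  }
  durs <- rep(c(1, 2, 4, 8), each = 5)
  av <- mk_av(durs, durs^2)        # <size> = duration^2 exactly
  expect_equal(fit_gamma(av), 2, tolerance = 1e-10)

  av1 <- mk_av(rep(1, 20), rep(3, 20))
  g <- fit_gamma(av1)
  expect_true(is.na(g))

  set.seed(41)
  durs <- sample(1:6, 300, replace = TRUE)
  sizes <- pmax(1L, as.integer(round(durs^1.7 * exp(rnorm(300, 0, 0.2)))))
  av2 <- mk_av(durs, sizes)
  # independent regression oracle on the binned means
  keep <- as.numeric(names(which(table(durs) >= 5)))
  mu <- vapply(keep, function(d) mean(sizes[durs == d]), numeric(1))
  oracle <- coef(lm(log(mu) ~ log(keep)))[[2]]
  expect_equal(fit_gamma(av2), oracle, tolerance = 1e-10)
})

test_that("kappa matches an independent oracle and is calibrated on true power laws", {
  # direct-formula oracle, written independently of the implementation
  kappa_oracle <- function(x, e_ref, xmin, xmax, m = 10) {
    beta <- exp(seq(log(xmin), log(xmax), length.out = m))
    xs <- xmin:xmax
    pm <- xs^(-e_ref) / sum(xs^(-e_ref))
    f_ref <- vapply(beta, function(b) sum(pm[xs <= floor(b)]), numeric(1))
    f_emp <- vapply(beta, function(b) mean(x <= floor(b)), numeric(1))
    1 + mean(f_ref - f_emp)
  }
  x <- sample_discrete_powerlaw(2e4, 1.4, 1, 64, seed = 51)
  expect_equal(kappa_powerlaw(x, 1.5, 1, 64),
               kappa_oracle(x, 1.5, 1, 64), tolerance = 1e-12)

  # calibration on exponent-1.5 samples over [1, 64]
  kaps <- vapply(1:20, function(s)
    kappa_powerlaw(sample_discrete_powerlaw(1e5, 1.5, 1, 64, seed = 600 + s),
                   1.5, 1, 64), numeric(1))
  expect_true(all(kaps > 0.97 & kaps < 1.03))

  # a steeper sample has a deficit of large events: kappa < 1;
  # a shallower one an excess: kappa > 1
  expect_lt(kappa_powerlaw(
    sample_discrete_powerlaw(1e5, 2.5, 1, 64, seed = 52), 1.5, 1, 64), 1)
  expect_gt(kappa_powerlaw(
    sample_discrete_powerlaw(1e5, 0.8, 1, 64, seed = 53), 1.5, 1, 64), 1)
})

test_that("generalized kappa scores shape deviance, not exponent value", {
  # internal consistency: kappa at the self-fit exponent equals kappa_gen
  x <- sample_discrete_powerlaw(2e4, 1.8, 1, 64, seed = 54)
  e_hat <- fit_discrete_powerlaw_mle(x, 1, 64)$exponent
  expect_equal(generalized_kappa(x, 1, 64),
               kappa_powerlaw(x, e_hat, 1, 64), tolerance = 1e-9)
  # power-law samples at any exponent score near 1
  for (e in c(0.8, 1.5, 2.2)) {
    x <- sample_discrete_powerlaw(1e5, e, 1, 64, seed = 100 * e)
    expect_equal(generalized_kappa(x, 1, 64), 1, tolerance = 0.03)
  }
  # a lognormal sample deviates more than a same-size power-law sample
  set.seed(55)
  ln <- pmin(pmax(round(rlnorm(1e4, 1.2, 0.8)), 1), 64)
  pl <- sample_discrete_powerlaw(1e4, 1.5, 1, 64, seed = 56)
  expect_gt(abs(generalized_kappa(ln, 1, 64) - 1),
            abs(generalized_kappa(pl, 1, 64) - 1))
  expect_true(is.na(generalized_kappa(integer(0), 1, 64)))
})

test_that("drop-off scale: recovered when present, beyond the sample when absent", {
  # generated with e = 1.5, s_c = 20
  x <- sample_discrete_powerlaw(1e5, 1.5, 1, 500, seed = 57, cutoff = 20)
  fit <- distribution_cutoff(x, 1)
  expect_gt(fit$cutoff, 15); expect_lt(fit$cutoff, 26)
  # pure truncated power law: no interior drop-off
  y <- sample_discrete_powerlaw(2e4, 1.5, 1, 100, seed = 58)
  fit2 <- distribution_cutoff(y, 1)
  expect_gt(fit2$cutoff, max(y))
  # degenerate: everything at xmin
  f3 <- distribution_cutoff(rep(1L, 100), 1)
  expect_true(is.na(f3$cutoff))
  expect_match(f3$reason, "tail")
})

test_that("cutoff fit agrees with a coarse 2-D likelihood grid", {
  x <- sample_discrete_powerlaw(5e3, 1.5, 1, 500, seed = 59, cutoff = 15)
  fit <- distribution_cutoff(x, 1)
  es <- seq(0.8, 2.2, by = 0.05); ss <- exp(seq(log(5), log(60), length.out = 40))
  xs <- 1:max(x)   # model support is the observed range
  ll <- outer(es, ss, Vectorize(function(e, s) {
    -e * sum(log(x)) - sum(x) / s - length(x) * log(sum(xs^(-e) * exp(-xs / s)))
  }))
  best <- arrayInd(which.max(ll), dim(ll))
  expect_equal(fit$exponent, es[best[1]], tolerance = 0.06)
  expect_equal(log(fit$cutoff), log(ss[best[2]]), tolerance = 0.15)
})

test_that("profile assembly propagates components and flags what is missing", {
  empty <- extract_avalanches(raster_from_matrix(matrix(0, 2, 50)))
  prof <- profile_at_scale(empty)
  vals <- unlist(prof[c("sigma", "alpha", "tau", "gamma", "delta",
                        "kappa", "kappa_gen", "cutoff")])
  expect_true(all(is.na(vals)))
  expect_setequal(names(prof$flags),
                  c("sigma", "alpha", "tau", "gamma", "delta",
                    "kappa", "kappa_gen", "cutoff"))

  set.seed(61)
  m <- matrix(rbinom(8 * 2e4, 1, 0.05), nrow = 8)
  prof2 <- profile_at_scale(extract_avalanches(raster_from_matrix(m)))
  expect_false(is.na(prof2$alpha))
  expect_false(is.na(prof2$kappa))
  expect_equal(prof2$scale_k, 1L)
})
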