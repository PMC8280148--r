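make_fp_table <- function(n, shift = 0, sd = 1, seed = 1) {
  set.seed(seed)
  nm <- mscr_feature_names()
  out <- as.data.frame(matrix(rnorm(n * 33, mean = shift, sd = sd),
                              nrow = n, dimnames = list(NULL, nm)))
  out
}

test_that("grouped fingerprints validate labels and canonical columns", {
  fp <- make_fp_table(6)
  expect_error(grouped_fingerprints(fp[, -1], rep(c("a", "b"), 3)),
               "canonical")
  expect_error(grouped_fingerprints(fp, rep("a", 6)), "2 groups")
  expect_error(grouped_fingerprints(fp, rep(c("a", "b"), 3),
                                    control_label = "c"), "not among")
  g <- grouped_fingerprints(fp, rep(c("a", "control"), 3))
  expect_equal(g$control_label, "control")
})

test_that("identical groups give zero statistics and p of 1", {
  fp <- make_fp_table(5, seed = 2)
  g <- grouped_fingerprints(rbind(fp, fp), rep(c("x", "y"), each = 5),
                            control_label = "x")
  tt <- per_feature_tests(g, "parametric")
  expect_equal(tt$statistic, rep(0, 33))
  expect_equal(tt$p_value, rep(1, 33))
})

test_that("well-separated groups are detected by both families, same direction", {
  a <- make_fp_table(20, shift = 0, seed = 3)
  b <- make_fp_table(20, shift = 10, seed = 4)
  g <- grouped_fingerprints(rbind(a, b), rep(c("control", "pat"), each = 20))
  tp <- per_feature_tests(g, "parametric")
  tn <- per_feature_tests(g, "nonparametric")
  expect_true(all(tp$p_value < 1e-6))
  expect_true(all(tn$p_value < 1e-6))
  z <- deviance_fingerprint(g, "pat")
  expect_true(all(z > 0))
})

test_that("more than two groups dispatches to ANOVA / Kruskal-Wallis", {
  fp <- rbind(make_fp_table(8, 0, seed = 5), make_fp_table(8, 0.2, seed = 6),
              make_fp_table(8, 5, seed = 7))
  g <- grouped_fingerprints(fp, rep(c("control", "g1", "g2"), each = 8))
  tp <- per_feature_tests(g, "parametric")
  tn <- per_feature_tests(g, "nonparametric")
  expect_equal(unique(tp$test), "anova")
  expect_equal(unique(tn$test), "kruskal-wallis")
  expect_true(all(tp$p_value < 0.01))
  # cross-check one feature against a direct aov call
  f1 <- fp[[mscr_feature_names()[1]]]
  lab <- factor(rep(c("control", "g1", "g2"), each = 8))
  ref <- anova(aov(f1 ~ lab))$`Pr(>F)`[1]
  expect_equal(tp$p_value[1], ref, tolerance = 1e-12)
})

test_that("features with too few usable values are flagged, not guessed", {
  fp <- make_fp_table(8, seed = 8)
  fp$a_sigma[1:4] <- NA
  g <- grouped_fingerprints(fp, rep(c("a", "b"), each = 4),
                            control_label = "a")
  tt <- per_feature_tests(g, "parametric")
  row <- tt[tt$feature == "a_sigma", ]
  expect_true(is.na(row$p_value))
  expect_match(row$note, "usable")
})

test_that("degenerate (constant) features are flagged rather than fatal", {
  fp <- make_fp_table(1, seed = 20)[rep(1, 8), ]  # zero variance everywhere
  g <- grouped_fingerprints(fp, rep(c("control", "t"), each = 4))
  tt <- per_feature_tests(g, "parametric")
  expect_true(all(is.na(tt$p_value)))
  expect_match(tt$note, "constant")
  res <- compare_groups(g, family = "parametric")
  expect_false(any(res$tests$significant))
})

test_that("BH step-up reproduces hand-computed masks", {
  expect_false(any(fdr_correct(rep(1, 10), 0.05)$significant))
  fc <- fdr_correct(c(p1 = 0.001, p2 = 0.02, p3 = 0.03, p4 = 0.5), q = 0.05)
  expect_equal(unname(fc$significant), c(TRUE, TRUE, TRUE, FALSE))
  # family of one reduces to the raw comparison
  expect_true(fdr_correct(c(only = 0.04), q = 0.05)$significant)
  # hand check of adjusted values: p_(i) * m / i, cummin from the top
  p <- c(0.001, 0.02, 0.03, 0.5)
  expect_equal(unname(fc$p_adjusted),
               rev(cummin(rev(p * 4 / seq_len(4)))))
  expect_error(fdr_correct(c(0.1, 1.2)), "0, 1")
})

test_that("BH mask is invariant to input order and excludes missing entries", {
  set.seed(9)
  p <- setNames(runif(33)^2, mscr_feature_names())
  p[c(4, 18)] <- NA
  f1 <- fdr_correct(p, 0.05)
  perm <- sample(33)
  f2 <- fdr_correct(p[perm], 0.05)
  expect_equal(f2$significant[names(p)], f1$significant)
  expect_true(all(is.na(f1$p_adjusted[c(4, 18)])))
  expect_false(any(f1$significant[c(4, 18)]))
  # family size is the count of non-missing p-values
  expect_equal(min(f1$p_adjusted, na.rm = TRUE),
               min(p.adjust(p[!is.na(p)], "BH")))
})

test_that("deviance fingerprints are control-referenced z-scores", {
  fp <- make_fp_table(10, seed = 10)
  g0 <- grouped_fingerprints(rbind(fp, fp),
                             rep(c("control", "t"), each = 10))
  expect_equal(unname(deviance_fingerprint(g0, "t")), rep(0, 33))

  # shift one feature of the target by exactly 2 control sds
  ctl <- make_fp_table(50, seed = 11)
  tgt <- ctl
  s <- sd(ctl$a_tau)
  tgt$a_tau <- tgt$a_tau + 2 * s
  g1 <- grouped_fingerprints(rbind(ctl, tgt),
                             rep(c("control", "t"), each = 50))
  z <- deviance_fingerprint(g1, "t")
  expect_equal(unname(z["a_tau"]), 2, tolerance = 1e-9)
  expect_equal(unname(z[setdiff(names(z), "a_tau")]), rep(0, 32),
               tolerance = 1e-9)

  # matches a direct spreadsheet-style recomputation on random groups
  a <- make_fp_table(12, seed = 12); b <- make_fp_table(9, shift = 1, seed = 13)
  g2 <- grouped_fingerprints(rbind(a, b),
                             c(rep("control", 12), rep("t", 9)))
  z2 <- deviance_fingerprint(g2, "t")
  for (feat in c("a_sigma", "kappa", "b_tau_delta")) {
    expect_equal(unname(z2[feat]),
                 (mean(b[[feat]]) - mean(a[[feat]])) / sd(a[[feat]]))
  }
  expect_error(deviance_fingerprint(g2, "nope"), "unknown")
})

test_that("compare_groups assembles tests, correction and deviance per family", {
  a <- make_fp_table(15, seed = 14)
  b <- make_fp_table(15, shift = 3, seed = 15)
  g <- grouped_fingerprints(rbind(a, b), rep(c("control", "pat"), each = 15))
  res <- compare_groups(g, family = "both", q = 0.01)
  expect_equal(nrow(res$tests), 66)
  expect_setequal(unique(res$tests$test), c("t", "mann-whitney"))
  expect_true(all(res$tests$significant))
  expect_named(res$deviance, c("feature", "pat"))
})
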