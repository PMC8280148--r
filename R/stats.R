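#' Grouped fingerprints for between-group comparison
#'
#' Binds a fingerprint table (rows = recordings, canonical 33 feature
#' columns) to a group label per row and a designated control group.
#'
#' @param features data frame containing the 33 canonical feature
#'   columns (extra columns such as `recording_id` are carried along).
#' @param labels group label per row.
#' @param control_label which label is the control group (default
#'   `"control"` if present, else the first level).
#' @return A list of class `grouped_fingerprints`.
#' @export
grouped_fingerprints <- function(features, labels, control_label = NULL) {
  features <- as.data.frame(features)
  miss <- setdiff(mscr_feature_names(), names(features))
  if (length(miss))
    stop("missing canonical features: ", paste(miss, collapse = ", "))
  labels <- as.character(labels)
  if (length(labels) != nrow(features))
    stop("'labels' must have one entry per row of 'features'")
  groups <- unique(labels)
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (is.null(control_label))
    control_label <- if ("control" %in% groups) "control" else groups[1L]
  if (!control_label %in% groups)
    stop(sprintf("control group '%s' not among labels", control_label))
  structure(list(features = features[, mscr_feature_names(), drop = FALSE],
                 labels = labels, control_label = control_label),
            class = "grouped_fingerprints")
}

#' @export
print.grouped_fingerprints <- function(x, ...) {
  cat("<grouped_fingerprints>", nrow(x$features), "recordings:\n")
  print(table(x$labels))
  cat("control group:", x$control_label, "\n")
  invisible(x)
}

#' Per-feature group tests across the 33 MsCr features
#'
#' For each feature: with two groups, a two-sided t-test (parametric) or
#' Mann-Whitney (nonparametric); with more, one-way ANOVA or
#' Kruskal-Wallis. Missing values are dropped per feature; a feature
#' with fewer than two usable values in any group gets a missing
#' p-value, flagged in the `note` column.
#'
#' @param g a [grouped_fingerprints()] object.
#' @param family `"parametric"` or `"nonparametric"`.
#' @return Data frame with columns `feature`, `test`, `statistic`,
#'   `p_value`, `note`.
#' @export
per_feature_tests <- function(g, family = c("parametric", "nonparametric")) {
  stopifnot(inherits(g, "grouped_fingerprints"))
  family <- match.arg(family)
  two <- length(unique(g$labels)) == 2L
  test_name <- if (two) {
    if (family == "parametric") "t" else "mann-whitney"
  } else {
    if (family == "parametric") "anova" else "kruskal-wallis"
  }
  rows <- lapply(mscr_feature_names(), function(feat) {
    v <- g$features[[feat]]
    ok <- is.finite(v)
    n_per <- tapply(ok, g$labels, sum)
    if (any(n_per < 2L))
      return(data.frame(feature = feat, test = test_name,
                        statistic = NA_real_, p_value = NA_real_,
                        note = "fewer than 2 usable values in some group"))
    x <- v[ok]; lab <- factor(g$labels[ok])
    res <- try(silent = TRUE, if (two) {
      sp <- split(x, lab)
      if (family == "parametric") {
        tt <- stats::t.test(sp[[1L]], sp[[2L]])
        c(tt$statistic, tt$p.value)
      } else {
        wt <- stats::wilcox.test(sp[[1L]], sp[[2L]], exact = FALSE)
        c(wt$statistic, wt$p.value)
      }
    } else {
      if (family == "parametric") {
        av <- stats::anova(stats::aov(x ~ lab))
        c(av$`F value`[1L], av$`Pr(>F)`[1L])
      } else {
        kt <- stats::kruskal.test(x, lab)
        c(kt$statistic, kt$p.value)
      }
    })
    if (inherits(res, "try-error"))
      return(data.frame(feature = feat, test = test_name,
                        statistic = NA_real_, p_value = NA_real_,
                        note = sub("\\n$", "", attr(res, "condition")$message)))
    data.frame(feature = feat, test = test_name, statistic = unname(res[1L]),
               p_value = unname(res[2L]), note = NA_character_)
  })
  do.call(rbind, rows)
}

#' Benjamini-Hochberg FDR correction over the feature family
#'
#' Step-up procedure at level `q` across the (non-missing) p-values of
#' the 33-feature family; missing entries are excluded from the family
#' size and stay missing in the output.
#'
#' @param pvalues named numeric vector of p-values in `[0, 1]`.
#' @param q acceptable false-discovery rate (default 0.05).
#' @return A list: `p_adjusted` (named, BH-adjusted), `significant`
#'   (named logical mask, `FALSE` where the input was missing), `q`.
#' @examples
#' fdr_correct(c(f1 = 0.001, f2 = 0.02, f3 = 0.03, f4 = 0.5), q = 0.05)
#' @export
fdr_correct <- function(pvalues, q = 0.05) {
  p <- as.numeric(pvalues)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  adj <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  adj[ok] <- stats::p.adjust(p[ok], method = "BH")
  sig <- !is.na(adj) & adj <= q
  names(adj) <- names(sig) <- names(pvalues)
  list(p_adjusted = adj, significant = sig, q = q)
}

#' Control-referenced z-score deviance fingerprint
#'
#' Per feature, `(mean(target) - mean(control)) / sd(control)`. A control
#' standard deviation of zero yields a missing z-score.
#'
#' @param g a [grouped_fingerprints()] object.
#' @param target_group label of the group to reference against control.
#' @return Named numeric vector of 33 z-scores.
#' @export
deviance_fingerprint <- function(g, target_group) {
  stopifnot(inherits(g, "grouped_fingerprints"))
  if (!target_group %in% g$labels)
    stop(sprintf("unknown group label '%s'", target_group))
  ctl <- g$features[g$labels == g$control_label, , drop = FALSE]
  tgt <- g$features[g$labels == target_group, , drop = FALSE]
  z <- vapply(mscr_feature_names(), function(feat) {
    cv <- ctl[[feat]][is.finite(ctl[[feat]])]
    tv <- tgt[[feat]][is.finite(tgt[[feat]])]
    if (!length(cv) || !length(tv)) return(NA_real_)
    s <- stats::sd(cv)
    if (!is.finite(s) || s == 0) return(NA_real_)
    (mean(tv) - mean(cv)) / s
  }, numeric(1))
  z
}

#' Full group comparison of a fingerprint table
#'
#' Convenience wrapper: runs [per_feature_tests()] for one or both test
#' families, applies [fdr_correct()] within each family, and computes
#' the z-score deviance fingerprint of every non-control group.
#'
#' @param g a [grouped_fingerprints()] object.
#' @param family `"parametric"`, `"nonparametric"` or `"both"`.
#' @param q FDR level (default 0.01, the conservative reporting level).
#' @return A list: `tests` (tidy table with columns `feature`, `test`,
#'   `statistic`, `p_value`, `p_adjusted`, `significant`), `deviance`
#'   (one z-score column per non-control group), `q`.
#' @export
compare_groups <- function(g, family = c("both", "parametric",
                                         "nonparametric"), q = 0.01) {
  stopifnot(inherits(g, "grouped_fingerprints"))
  family <- match.arg(family)
  fams <- if (family == "both") c("parametric", "nonparametric") else family
  tests <- do.call(rbind, lapply(fams, function(f) {
    tt <- per_feature_tests(g, f)
    p <- stats::setNames(tt$p_value, tt$feature)
    fc <- fdr_correct(p, q)
    tt$p_adjusted <- unname(fc$p_adjusted)
    tt$significant <- unname(fc$significant)
    tt
  }))
  others <- setdiff(unique(g$labels), g$control_label)
  dev <- as.data.frame(lapply(others, function(gr) deviance_fingerprint(g, gr)))
  names(dev) <- others
  dev <- cbind(data.frame(feature = mscr_feature_names()), dev)
  rownames(dev) <- NULL
  list(tests = tests, deviance = dev, q = q)
}
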