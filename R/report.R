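#' Two-group comparison of a morphometric
#'
#' Two-sided comparison of a per-object metric between two experimental
#' groups, using the conventions of EM morphometry studies: Welch's
#' unequal-variance t-test, or the non-parametric Mann-Whitney (Wilcoxon
#' rank-sum) test. The choice is an explicit flag, never automatic. The
#' Mann-Whitney p-value uses the exact null distribution when the combined
#' n is at most 20 and no ties are present, and the normal approximation
#' with tie correction otherwise. Comparisons of more than two groups are
#' deliberately out of scope (use pairwise comparisons); requesting one
#' raises an error.
#'
#' @param values_a,values_b numeric vectors (each n >= 2).
#' @param test `"welch_t"` or `"mann_whitney"`.
#' @param metric optional metric name carried into the result.
#' @param groups optional length-2 character vector of group labels.
#' @return An object of class `"group_comparison"`: `metric`, `groups`,
#'   `n`, `test`, `statistic`, `p_value`, `stars`, `degenerate` (TRUE when
#'   both groups are constant and equal, in which case p = 1 by
#'   convention).
#' @export
compare_groups <- function(values_a, values_b,
                           test = c("welch_t", "mann_whitney"),
                           metric = "metric", groups = c("A", "B")) {
  test <- match.arg(test)
  values_a <- as.numeric(values_a); values_b <- as.numeric(values_b)
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stopf("each group needs n >= 2 (got %d and %d)",
          length(values_a), length(values_b))
  }
  degenerate <- FALSE
  if (test == "welch_t") {
    if (var(values_a) == 0 && var(values_b) == 0) {
      # zero variance in both groups: t is undefined; identical constants
      # are reported as no evidence of difference
      degenerate <- TRUE
      statistic <- NA_real_
      p <- if (values_a[1] == values_b[1]) 1 else 0
    } else {
      ht <- t.test(values_a, values_b, var.equal = FALSE)
      statistic <- unname(ht$statistic)
      p <- ht$p.value
    }
  } else {
    n_tot <- length(values_a) + length(values_b)
    ties <- anyDuplicated(c(values_a, values_b)) > 0L
    exact <- n_tot <= 20L && !ties
    ht <- suppressWarnings(
      wilcox.test(values_a, values_b, exact = exact, correct = TRUE))
    statistic <- unname(ht$statistic)
    p <- ht$p.value
  }
  structure(list(metric = metric, groups = groups,
                 n = c(length(values_a), length(values_b)), test = test,
                 statistic = statistic, p_value = p, stars = stars(p),
                 degenerate = degenerate),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: %s vs %s (n = %d, %d), %s: statistic = %s, p = %.4g %s\n",
              x$metric, x$groups[1], x$groups[2], x$n[1], x$n[2], x$test,
              format(x$statistic), x$p_value, x$stars))
  invisible(x)
}

#' Significance stars
#'
#' The star convention used throughout: `*` for p < 0.05, `**` for
#' p < 0.01, `***` for p < 0.001, `****` for p < 0.0001 and `"ns"`
#' otherwise. Thresholds are strict inequalities, so p = 0.05 is `"ns"`.
#'
#' @param p_value p-value in \[0, 1\].
#' @return One of `"ns"`, `"*"`, `"**"`, `"***"`, `"****"`.
#' @export
stars <- function(p_value) {
  if (!is.finite(p_value) || p_value < 0 || p_value > 1) {
    stopf("p_value must be in [0, 1]")
  }
  if (p_value < 0.0001) "****"
  else if (p_value < 0.001) "***"
  else if (p_value < 0.01) "**"
  else if (p_value < 0.05) "*"
  else "ns"
}

#' Blinded-workflow provenance metadata
#'
#' Unbiased morphometry requires that fixation, imaging and quantification
#' be performed by separate, blinded individuals. Software cannot enforce
#' blinding; it can record who did what so the provenance is auditable in
#' every report.
#'
#' @param fixer,imager,quantifier free-text identifiers.
#' @return A named list of class `"analysis_metadata"`.
#' @export
analysis_metadata <- function(fixer = NA_character_, imager = NA_character_,
                              quantifier = NA_character_) {
  structure(list(fixer = fixer, imager = imager, quantifier = quantifier,
                 note = paste("fixation, imaging and quantification should be",
                              "performed by separate blinded individuals")),
            class = "analysis_metadata")
}

#' Group-comparison report from tidy measurements
#'
#' Takes tidy measurements (columns `group`, `metric`, `value`), compares
#' the two groups for each requested metric, and optionally writes a
#' Markdown report with per-metric tables, star annotations and the
#' blinded-workflow provenance block.
#'
#' @param df data.frame with columns `group`, `metric`, `value`.
#' @param metrics metrics to compare (default: all present).
#' @param test `"welch_t"` or `"mann_whitney"`.
#' @param metadata an [analysis_metadata()].
#' @param output optional path of a Markdown report to write.
#' @return data.frame with one row per metric: group ns, statistic,
#'   p_value, stars.
#' @export
report_comparisons <- function(df, metrics = NULL,
                               test = c("welch_t", "mann_whitney"),
                               metadata = analysis_metadata(),
                               output = NULL) {
  test <- match.arg(test)
  need <- c("group", "metric", "value")
  if (!all(need %in% names(df))) {
    stopf("input must have columns %s", paste(need, collapse = ", "))
  }
  gl <- sort(unique(as.character(df$group)))
  if (length(gl) != 2L) {
    stopf(paste("%d groups found; only two-group comparisons are supported",
                "(for more groups run pairwise comparisons explicitly)"),
          length(gl))
  }
  metrics <- metrics %||% sort(unique(as.character(df$metric)))
  rows <- lapply(metrics, function(m) {
    a <- df$value[df$group == gl[1] & df$metric == m]
    b <- df$value[df$group == gl[2] & df$metric == m]
    cmp <- compare_groups(a, b, test, metric = m, groups = gl)
    data.frame(metric = m, group_a = gl[1], group_b = gl[2],
               n_a = cmp$n[1], n_b = cmp$n[2],
               mean_a = mean(a), mean_b = mean(b), test = test,
               statistic = cmp$statistic, p_value = cmp$p_value,
               stars = cmp$stars)
  })
  out <- do.call(rbind, rows)
  if (!is.null(output)) {
    lines <- c("# Morphometry group comparison", "",
               sprintf("- groups: %s vs %s", gl[1], gl[2]),
               sprintf("- test: %s (two-sided)", test),
               sprintf("- fixer: %s / imager: %s / quantifier: %s",
                       metadata$fixer, metadata$imager, metadata$quantifier),
               sprintf("- note: %s", metadata$note), "",
               "| metric | n | mean A | mean B | p | stars |",
               "|---|---|---|---|---|---|",
               sprintf("| %s | %d, %d | %.4g | %.4g | %.3g | %s |",
                       out$metric, out$n_a, out$n_b, out$mean_a, out$mean_b,
                       out$p_value, out$stars))
    writeLines(lines, output)
  }
  out
}
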