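#' Mood's median test with a chi-squared/N effect size
#'
#' Counts, per group, the values strictly above versus not above the pooled
#' median (ties count as "not above"), and tests the resulting 2 x K table
#' with Pearson's chi-squared statistic on K - 1 degrees of freedom without
#' continuity correction. The effect size is `chi2 / N`, a standardized
#' chi-squared bounded by 1 for two groups.
#'
#' @param ... Either a single list of numeric vectors, or two or more
#'   numeric vectors.
#' @return Object of class `median_test_result`: `chi2`, `df`, `p`,
#'   `effect_size`, `contingency` (2 x K), `pooled_median`, `n`.
#' @export
median_test <- function(...) {
  args <- list(...)
  groups <- if (length(args) == 1 && is.list(args[[1]]) &&
                !is.numeric(args[[1]])) args[[1]] else args
  if (length(groups) < 2) stop("need at least two groups")
  groups <- lapply(groups, function(g) g[is.finite(g)])
  if (any(lengths(groups) < 1)) stop("every group needs at least one value")
  pooled <- unlist(groups, use.names = FALSE)
  m <- stats::median(pooled)
  above <- vapply(groups, function(g) sum(g > m), 0L)
  notab <- lengths(groups) - above
  tab <- rbind(above = above, not_above = notab)
  colnames(tab) <- names(groups) %||% paste0("g", seq_along(groups))
  if (any(rowSums(tab) == 0))
    stop("degenerate contingency table (all values on one side of the ",
         "pooled median); the median test is undefined")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  n <- sum(tab)
  structure(list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
                 p = ct$p.value, effect_size = unname(ct$statistic) / n,
                 contingency = tab, pooled_median = m, n = n),
            class = "median_test_result")
}

#' @export
print.median_test_result <- function(x, ...) {
  cat(sprintf(
    "<median_test> chi2 = %.4f (df %d), p = %.4g, chi2/N = %.4f\n",
    x$chi2, x$df, x$p, x$effect_size))
  cat(sprintf("  pooled median = %.4g over N = %d\n", x$pooled_median, x$n))
  invisible(x)
}

#' Scott's-rule histogram bin edges
#'
#' Bin width `h = 3.49 * sd * n^(-1/3)`; the bin count is
#' `ceiling(range / h)` and the edges span `[min, max]` exactly.
#'
#' @param values Numeric vector, `n >= 2`.
#' @return Numeric vector of bin edges, with attribute `width` (the realized
#'   edge spacing). Zero spread falls back to a single bin with a warning.
#' @export
scott_bins <- function(values) {
  v <- values[is.finite(values)]
  n <- length(v)
  if (n < 2) stop("need at least 2 values")
  s <- stats::sd(v)
  if (s == 0) {
    warning("zero standard deviation; single-bin fallback")
    return(structure(c(v[1] - 0.5, v[1] + 0.5), width = 1))
  }
  h <- 3.49 * s * n^(-1 / 3)
  k <- ceiling((max(v) - min(v)) / h)
  edges <- seq(min(v), max(v), length.out = k + 1L)
  structure(edges, width = diff(edges[1:2]))
}

#' Per-repeat-median t-test with Cohen's d
#'
#' Summarizes each experimental repeat by the median of its records, then
#' compares the means of these medians between the two groups with an
#' independent two-sample t-test (equal-variance by default, matching
#' conventional reporting for small balanced designs; Welch by flag).
#' Cohen's d uses the pooled standard deviation and is positive when the
#' first group's mean exceeds the second's.
#'
#' @param values Numeric record-level values.
#' @param repeat_id Repeat identifier per record.
#' @param group Group label per record (exactly two distinct labels).
#' @param welch Use the Welch (unequal-variance) t-test.
#' @return Object of class `repeat_test_result`: `medians` (data.frame
#'   group, repeat_id, median), `group_means`, `t`, `df`, `p`, `cohens_d`,
#'   `groups`.
#' @export
repeat_summary_test <- function(values, repeat_id, group, welch = FALSE) {
  keep <- is.finite(values)
  values <- values[keep]
  repeat_id <- as.character(repeat_id)[keep]
  group <- as.character(group)[keep]
  gl <- unique(group)
  if (length(gl) != 2) stop("need exactly two groups, got ", length(gl))
  med <- stats::aggregate(values,
                          by = list(group = group, repeat_id = repeat_id),
                          FUN = stats::median)
  names(med)[3] <- "median"
  m1 <- med$median[med$group == gl[1]]
  m2 <- med$median[med$group == gl[2]]
  if (length(m1) < 2 || length(m2) < 2)
    stop("need >= 2 repeats per group")
  tt <- stats::t.test(m1, m2, var.equal = !welch)
  sp <- sqrt(((length(m1) - 1) * stats::var(m1) +
              (length(m2) - 1) * stats::var(m2)) /
             (length(m1) + length(m2) - 2))
  d <- if (sp == 0) 0 else (mean(m1) - mean(m2)) / sp
  structure(list(medians = med,
                 group_means = stats::setNames(c(mean(m1), mean(m2)), gl),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, cohens_d = d, groups = gl),
            class = "repeat_test_result")
}

#' @export
print.repeat_test_result <- function(x, ...) {
  cat(sprintf(
    "<repeat_test> %s vs %s: means %.4g / %.4g, t = %.3f, p = %.4g, d = %.3f\n",
    x$groups[1], x$groups[2], x$group_means[1], x$group_means[2],
    x$t, x$p, x$cohens_d))
  invisible(x)
}
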