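#' Comparison protocol: summaries, frequency curves, correlations, tests
#'
#' The reporting toolkit used to compare 2D and 3D measurement sets:
#' mean +/- SEM summary tables, relative-frequency curves over fixed bins
#' (0.08 um bins for lengths, 0.06 um^2 for areas, 0.03 um^3 for volumes),
#' Spearman rank correlations, and two-group (Mann--Whitney) or multi-group
#' (one-way ANOVA) location tests.
#'
#' @name stats_compare
#' @keywords internal
NULL

#' Summary table for one measured variable
#'
#' @param values Numeric vector, n >= 2.
#' @param variable Variable name for the report.
#' @param units Unit string (um, um^2, um^3).
#' @return One-row `data.frame`: `variable`, `n`, `mean`, `sem`, `min`,
#'   `max`, `units`. The SEM uses the n-1 denominator standard deviation.
#' @examples
#' summarize_values(c(1, 2, 3), "demo", "um")
#' @export
summarize_values <- function(values, variable = "value", units = "") {
  if (anyNA(values)) values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) stop("need at least 2 values: SEM is undefined", call. = FALSE)
  data.frame(variable = variable, n = n,
             mean = mean(values),
             sem = stats::sd(values) / sqrt(n),
             min = min(values), max = max(values),
             units = units, stringsAsFactors = FALSE)
}

#' Relative-frequency curve over fixed bins
#'
#' Bins are half-open `[lo, hi)` except the last, which is closed; values
#' beyond the last bin are counted into it (the overflow count is attached
#' as attribute `"n_overflow"` and reported with a warning), so frequencies
#' always sum to one.
#'
#' @param values Numeric vector (non-empty), all `>= start`.
#' @param start Left edge of the first bin.
#' @param bin_width Bin width (> 0).
#' @param n_bins Number of bins (>= 1).
#' @return A `data.frame` with `bin_lo`, `bin_hi`, `mid`, `count`, `freq`;
#'   `sum(freq) == 1`.
#' @examples
#' frequency_curve(c(0.05, 0.05, 0.15), start = 0, bin_width = 0.1,
#'                 n_bins = 2)
#' @export
frequency_curve <- function(values, start, bin_width, n_bins) {
  if (length(values) == 0) stop("empty input", call. = FALSE)
  if (anyNA(values)) values <- values[!is.na(values)]
  if (length(values) == 0) stop("empty input", call. = FALSE)
  stopifnot(bin_width > 0, n_bins >= 1)
  if (any(values < start)) {
    stop("values below the first bin edge; lower `start`", call. = FALSE)
  }
  idx <- floor((values - start) / bin_width) + 1
  overflow <- sum(idx > n_bins)
  if (overflow > 0) {
    warning(overflow, " value(s) beyond the last bin counted into it")
    idx[idx > n_bins] <- n_bins
  }
  counts <- tabulate(idx, nbins = n_bins)
  lo <- start + (seq_len(n_bins) - 1) * bin_width
  out <- data.frame(bin_lo = lo, bin_hi = lo + bin_width,
                    mid = lo + bin_width / 2,
                    count = counts, freq = counts / length(values))
  attr(out, "n_overflow") <- overflow
  out
}

#' Spearman rank correlation
#'
#' Rank-based correlation with mid-ranks for ties: the Pearson correlation
#' of the two rank vectors, computed explicitly. Equal to the classical
#' `1 - 6 sum(d^2) / (n (n^2 - 1))` formula when there are no ties.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, neither constant.
#' @return Correlation in `[-1, 1]`; symmetric in its arguments.
#' @examples
#' spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4)) # 0.8
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length", call. = FALSE)
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sx <- sqrt(sum(dx^2)); sy <- sqrt(sum(dy^2))
  if (sx == 0 || sy == 0) {
    stop("constant input: rank correlation undefined", call. = FALSE)
  }
  sum(dx * dy) / (sx * sy)
}

#' Two- or multi-group location comparison
#'
#' Two groups are compared with the Mann--Whitney rank-sum test (exact for
#' small untied samples, otherwise the continuity-corrected normal
#' approximation, as provided by [stats::wilcox.test()]); three or more
#' groups with the one-way ANOVA F test.
#'
#' @param ... Two or more numeric vectors, or a single list of them.
#' @return A list of class `"group_comparison"`: `test` (`"mann_whitney"`
#'   or `"anova_oneway"`), `statistic`, `p_value`, `n` (per-group sizes).
#' @examples
#' compare_groups(rnorm(20), rnorm(20, 2))$test
#' @export
compare_groups <- function(...) {
  groups <- list(...)
  if (length(groups) == 1 && is.list(groups[[1]])) groups <- groups[[1]]
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) < 2)) {
    stop("every group needs at least 2 observations", call. = FALSE)
  }
  ns <- vapply(groups, length, integer(1))
  if (length(groups) == 2) {
    ht <- stats::wilcox.test(groups[[1]], groups[[2]], correct = TRUE)
    out <- list(test = "mann_whitney",
                statistic = unname(ht$statistic),
                p_value = ht$p.value, n = ns)
  } else {
    values <- unlist(groups)
    g <- factor(rep(seq_along(groups), ns))
    fit <- stats::aov(values ~ g)
    tab <- summary(fit)[[1]]
    out <- list(test = "anova_oneway",
                statistic = tab[["F value"]][1],
                p_value = tab[["Pr(>F)"]][1], n = ns)
  }
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s)\n", x$test,
              x$statistic, x$p_value, paste(x$n, collapse = ", ")))
  invisible(x)
}

#' Default histogram specifications for the three variable families
#'
#' Lengths (SAL, PSD_L) use 10 bins of 0.08 um; areas (head area, SAS,
#' SAL_S, PSD_S) 9 bins of 0.06 um^2; volumes 10 bins of 0.03 um^3. All
#' start at zero (the bin origin is a reporting convention, stated here
#' once).
#'
#' @param family `"length"`, `"area"` or `"volume"`.
#' @return List with `start`, `bin_width`, `n_bins`.
#' @export
histogram_spec <- function(family = c("length", "area", "volume")) {
  switch(match.arg(family),
         length = list(start = 0, bin_width = 0.08, n_bins = 10),
         area   = list(start = 0, bin_width = 0.06, n_bins = 9),
         volume = list(start = 0, bin_width = 0.03, n_bins = 10))
}
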