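# Severing-rate and crossover-density quantification plus the two group
# comparison tests used throughout: Mann-Whitney U for non-normal data
# (exact for small samples) and Student's t test otherwise.

#' Severing rates per cell and group summary
#'
#' Per-cell rate = event count / (area x duration); the group summary is the
#' mean +/- SD across cells (the reporting convention for severing rates;
#' anisotropy scores are conventionally summarized mean +/- SE, see `se`).
#'
#' @param record a `severing_record` ([make_severing_series()]) or a list
#'   with `events` (`cell` column), `cell_areas`, `duration`.
#' @return a `rate_summary`: `per_cell` (events um^-2 min^-1), `mean`, `sd`,
#'   `se`, `n`.
#' @export
severing_rate <- function(record) {
  if (any(record$cell_areas <= 0) || any(record$duration <= 0))
    stop("areas and durations must be positive")
  n <- length(record$cell_areas)
  counts <- tabulate(record$events$cell, nbins = n)
  rates <- counts / (record$cell_areas * record$duration)
  structure(list(per_cell = rates, mean = mean(rates),
                 sd = stats::sd(rates),
                 se = stats::sd(rates) / sqrt(n), n = n),
            class = "rate_summary")
}

#' Crossover density and percent change between two timepoints
#'
#' Densities are normalized to events per 10 um^2; the percent change
#' between group means is rounded to the nearest integer (the convention
#' behind "means 11.0 -> 12 per 10 um^2 = +9%").
#'
#' @param counts_t1,counts_t2 per-window crossover counts at the two
#'   timepoints (same windows).
#' @param window_area window area (um^2); recycled.
#' @return list: `density_t1`, `density_t2` (per 10 um^2), `mean_t1`,
#'   `mean_t2`, `se_t1`, `se_t2`, `percent_change` (integer, NA with a
#'   flag when the baseline mean is zero).
#' @export
crossover_density <- function(counts_t1, counts_t2, window_area) {
  stopifnot(length(counts_t1) == length(counts_t2), all(window_area > 0))
  wa <- rep_len(window_area, length(counts_t1))
  d1 <- counts_t1 / wa * 10
  d2 <- counts_t2 / wa * 10
  m1 <- mean(d1); m2 <- mean(d2)
  pc <- if (m1 == 0) NA_real_ else round(100 * (m2 - m1) / m1)
  list(density_t1 = d1, density_t2 = d2, mean_t1 = m1, mean_t2 = m2,
       se_t1 = stats::sd(d1) / sqrt(length(d1)),
       se_t2 = stats::sd(d2) / sqrt(length(d2)),
       percent_change = pc, undefined_baseline = m1 == 0)
}

#' Two-group comparison (Mann-Whitney U or t test)
#'
#' Mann-Whitney: exact two-sided p-value when the combined sample size is at
#' most 20 and there are no ties, otherwise the normal approximation with
#' tie correction (the behavior of [stats::wilcox.test()]). The reported U
#' statistic counts pairs won by `a`.
#'
#' @param a,b numeric samples.
#' @param test `"mann_whitney"` or `"t_test"`.
#' @return list: `test`, `statistic`, `p_value`, `summary` (per group:
#'   mean, se, n).
#' @export
compare_groups <- function(a, b, test = c("mann_whitney", "t_test")) {
  test <- match.arg(test)
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  summ <- data.frame(
    group = c("a", "b"), n = c(length(a), length(b)),
    mean = c(mean(a), mean(b)),
    se = c(stats::sd(a) / sqrt(length(a)), stats::sd(b) / sqrt(length(b))))
  if (test == "mann_whitney") {
    exact <- (length(a) + length(b)) <= 20L &&
      !any(duplicated(c(a, b)))
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                              correct = !exact))
    list(test = "mann_whitney", statistic = unname(wt$statistic),
         p_value = wt$p.value, summary = summ)
  } else {
    if (length(a) < 2L || length(b) < 2L)
      stop("t test needs at least 2 observations per group")
    tt <- stats::t.test(a, b)
    list(test = "t_test", statistic = unname(tt$statistic),
         p_value = tt$p.value, summary = summ)
  }
}
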