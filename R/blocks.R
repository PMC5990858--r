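#' Assign clock hours to the three 8-hour time blocks
#'
#' Trichotomizes the day into night (0:00--7:59), work (8:00--15:59) and
#' evening (16:00--23:59), separating unstructured nighttime, structured
#' office hours, and leisure time.
#'
#' @param hour Integer vector of clock hours in 0--23.
#' @return Factor with levels `night`, `work`, `evening`.
#' @export
assign_block <- function(hour) {
  if (!is.numeric(hour) || any(!is.finite(hour)) || any(hour != floor(hour)) ||
      any(hour < 0) || any(hour > 23))
    stop("hour must be integer(s) in 0..23", call. = FALSE)
  factor(ifelse(hour < 8, "night", ifelse(hour < 16, "work", "evening")),
         levels = c("night", "work", "evening"))
}

#' Per-block mean and SD of raw hourly RSV
#'
#' Sorts every hourly value of a validated series into its time block and
#' summarizes each block by its mean, sample SD and count. The analysis is
#' run on raw RSV, not on reconstructed values.
#'
#' @param series An [hourly_series()] on a uniform hourly grid.
#' @return A data frame (class `block_summary`) with columns `block`, `n`,
#'   `mean`, `sd`.
#' @export
block_summaries <- function(series) {
  stopifnot(inherits(series, "hourly_series"))
  assert_uniform(series)
  block <- assign_block(series_hours(series))
  out <- data.frame(
    block = levels(block),
    n = as.integer(tabulate(block, 3L)),
    mean = as.numeric(tapply(series$values, block, mean)),
    sd = as.numeric(tapply(series$values, block, stats::sd)),
    stringsAsFactors = FALSE)
  class(out) <- c("block_summary", "data.frame")
  attr(out, "term") <- series$term
  out
}

#' Time-block ANOVA with Bonferroni-corrected post-hoc comparisons
#'
#' One-way equal-variance ANOVA of the series values over the three time
#' blocks, followed by the three pairwise two-sided pooled-variance t tests
#' with Bonferroni correction (raw p multiplied by 3, capped at 1). With
#' `unit = "hour"` every hourly value is an observation (n = 8 x days per
#' block); with `unit = "day"` each day contributes one mean per block
#' (n = days per block), which respects within-day dependence at the cost of
#' power.
#'
#' @param series An [hourly_series()] covering complete days.
#' @param alpha Significance level in (0, 0.5\]; default 0.05.
#' @param unit `"hour"` (default) or `"day"`.
#' @return A list of class `block_analysis`: `summary` (the
#'   [block_summaries()] table for the chosen unit), `comparisons` (data
#'   frame with `block_a`, `block_b`, `mean_diff`, `p_raw`, `p_bonferroni`),
#'   `F`, `p`, `alpha`, `unit`, `term`.
#' @export
block_anova_posthoc <- function(series, alpha = 0.05,
                                unit = c("hour", "day")) {
  stopifnot(inherits(series, "hourly_series"))
  unit <- match.arg(unit)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 0.5)
    stop("alpha must lie in (0, 0.5]", call. = FALSE)
  assert_uniform(series)
  hour <- series_hours(series)
  if (unit == "hour") {
    obs <- series$values
    block <- assign_block(hour)
  } else {
    f <- fold_days(series)
    blk <- assign_block(0:23)
    obs <- as.vector(vapply(
      levels(blk), function(b) rowMeans(f$matrix[, blk == b, drop = FALSE]),
      numeric(nrow(f$matrix))))
    block <- factor(rep(levels(blk), each = nrow(f$matrix)),
                    levels = levels(blk))
  }
  if (any(tabulate(block, 3L) < 2L))
    stop("each block needs >= 2 observations", call. = FALSE)
  if (stats::var(obs) == 0)
    stop("degenerate variance: constant series", call. = FALSE)

  ow <- stats::oneway.test(obs ~ block, var.equal = TRUE)

  lv <- levels(block)
  pairs <- utils::combn(lv, 2L)
  m <- tapply(obs, block, mean)
  comp <- data.frame(
    block_a = pairs[1L, ], block_b = pairs[2L, ],
    mean_diff = m[pairs[1L, ]] - m[pairs[2L, ]],
    p_raw = NA_real_, row.names = NULL, stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    sel <- block %in% pairs[, i]
    tt <- stats::t.test(obs[sel] ~ droplevels(block[sel]), var.equal = TRUE)
    comp$p_raw[i] <- tt$p.value
  }
  comp$p_bonferroni <- pmin(1, 3 * comp$p_raw)

  summ <- data.frame(
    block = lv,
    n = as.integer(tabulate(block, 3L)),
    mean = as.numeric(m),
    sd = as.numeric(tapply(obs, block, stats::sd)),
    stringsAsFactors = FALSE)
  class(summ) <- c("block_summary", "data.frame")

  structure(
    list(summary = summ, comparisons = comp,
         F = unname(ow$statistic), p = unname(ow$p.value),
         alpha = alpha, unit = unit, term = series$term),
    class = "block_analysis")
}

#' @export
print.block_analysis <- function(x, ...) {
  cat(sprintf("<block_analysis> term='%s'  unit=%s  F=%.3g  p=%.3g\n",
              x$term, x$unit, x$F, x$p))
  print.data.frame(x$summary, row.names = FALSE)
  print.data.frame(x$comparisons, row.names = FALSE, digits = 4)
  invisible(x)
}
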