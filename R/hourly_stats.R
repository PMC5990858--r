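#' One-way ANOVA across the 24 hourly distributions
#'
#' Treats the folded days as 24 groups (one per clock hour) with the days as
#' replicates and tests equality of the hourly means with the classical
#' equal-variance one-way ANOVA.
#'
#' @param folded A `folded_days` object.
#' @return List with `F`, `p`, `df_between`, `df_within`.
#' @export
hourly_anova <- function(folded) {
  stopifnot(inherits(folded, "folded_days"))
  m <- folded$matrix
  if (nrow(m) < 2L) stop("need at least 2 days", call. = FALSE)
  values <- as.vector(m)
  groups <- factor(rep(0:23, each = nrow(m)))
  if (all(apply(m, 2L, stats::var) == 0) &&
      length(unique(colMeans(m))) == 1L)
    stop("degenerate variance: all groups constant and equal", call. = FALSE)
  ow <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  list(F = unname(ow$statistic), p = unname(ow$p.value),
       df_between = unname(ow$parameter[1L]),
       df_within = unname(ow$parameter[2L]))
}

#' Tukey-Kramer all-pairs comparison of hourly distributions
#'
#' For every pair of clock hours (i, j) computes the studentized-range
#' statistic on the pooled within-group variance with the Tukey-Kramer
#' unequal-n correction (which reduces to classic Tukey HSD for the equal
#' group sizes produced by [fold_days()]) and the corresponding adjusted
#' p-value. The directional indicator `greater[i, j]` is `TRUE` when the
#' adjusted p-value is below `alpha` and hour i's mean exceeds hour j's —
#' the "interest at hour i is significantly greater than at hour j" dots of
#' the hour-versus-hour significance plot.
#'
#' @param folded A `folded_days` object (per the study's convention this is
#'   usually built from the band-pass reconstructed, mean-restored series;
#'   raw RSV folding works identically).
#' @param alpha Familywise significance level in (0, 0.5\]; default 0.05.
#' @return An object of class `significance_matrix`: logical `greater`
#'   (24 x 24), symmetric `p_adjusted` with unit diagonal, `means`,
#'   `n_by_hour`, `alpha`.
#' @export
tukey_kramer <- function(folded, alpha = 0.05) {
  stopifnot(inherits(folded, "folded_days"))
  values <- as.vector(folded$matrix)
  groups <- factor(rep(0:23, each = nrow(folded$matrix)), levels = 0:23)
  out <- pairwise_tukey(values, groups, alpha = alpha)
  out$n_by_hour <- out$n_by_group
  out
}

#' Tukey-Kramer procedure for arbitrary groups
#'
#' The general machinery behind [tukey_kramer()]: pooled within-group
#' variance, studentized-range adjusted p-values
#' `p = P(q_{k, N-k} > |m_i - m_j| / sqrt((MSE/2)(1/n_i + 1/n_j)))`,
#' and directional significance by comparing group means.
#'
#' @param values Numeric vector of observations.
#' @param groups Factor of the same length; every level needs >= 2
#'   observations.
#' @param alpha Familywise significance level in (0, 0.5\].
#' @return A `significance_matrix` over the factor levels.
#' @export
pairwise_tukey <- function(values, groups, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 0.5)
    stop("alpha must lie in (0, 0.5]", call. = FALSE)
  groups <- as.factor(groups)
  stopifnot(length(values) == length(groups))
  k <- nlevels(groups)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  n_g <- tabulate(groups, nbins = k)
  if (any(n_g < 2L)) stop("every group needs >= 2 observations", call. = FALSE)
  m_g <- tapply(values, groups, mean)
  N <- length(values)
  df <- N - k
  mse <- sum((values - m_g[as.integer(groups)])^2) / df
  if (mse == 0 && length(unique(m_g)) == 1L)
    stop("degenerate variance: all groups constant and equal", call. = FALSE)

  diff_m <- outer(m_g, m_g, "-")
  se <- sqrt((mse / 2) * outer(1 / n_g, 1 / n_g, "+"))
  q <- abs(diff_m) / se
  p <- matrix(stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE),
              k, k, dimnames = list(levels(groups), levels(groups)))
  diag(p) <- 1
  greater <- (p < alpha) & (diff_m > 0)
  diag(greater) <- FALSE
  structure(
    list(greater = greater, p_adjusted = p,
         means = stats::setNames(as.numeric(m_g), levels(groups)),
         n_by_group = stats::setNames(n_g, levels(groups)),
         alpha = alpha, mse = mse, df = df),
    class = "significance_matrix")
}

#' @export
print.significance_matrix <- function(x, ...) {
  cat(sprintf(
    "<significance_matrix> %d groups, alpha=%.3g, %d directional significant pair(s)\n",
    nrow(x$greater), x$alpha, sum(x$greater)))
  invisible(x)
}

#' @export
as.data.frame.significance_matrix <- function(x, ...) {
  lv <- rownames(x$greater)
  idx <- which(upper.tri(x$p_adjusted) | lower.tri(x$p_adjusted),
               arr.ind = TRUE)
  data.frame(
    hour_i = lv[idx[, 1L]], hour_j = lv[idx[, 2L]],
    mean_diff = x$means[idx[, 1L]] - x$means[idx[, 2L]],
    p_adjusted = x$p_adjusted[idx],
    greater = x$greater[idx],
    row.names = NULL, stringsAsFactors = FALSE)
}
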