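#' Fold an hourly series into a days-by-hours matrix
#'
#' Reshapes a uniformly hourly series into a matrix with one row per day and
#' exactly 24 columns, so that entry (d, h) is the value at day d, clock
#' hour h (hour h labels the window \[h:00, h+1:00)). Leading samples before
#' the first midnight and trailing samples after the last complete day are
#' trimmed with a warning.
#'
#' @param series An [hourly_series()] on a uniform hourly grid covering at
#'   least two complete days.
#' @return An object of class `folded_days`: `matrix` (days x 24),
#'   `day_labels` (dates), `hour_labels` (0--23), `term`.
#' @export
fold_days <- function(series) {
  stopifnot(inherits(series, "hourly_series"))
  assert_uniform(series)
  h <- series_hours(series)
  v <- series$values
  ts <- series$timestamps
  if (h[1] != 0L) {
    drop <- 24L - h[1]
    warning("trimming ", drop, " leading sample(s) before the first midnight",
            call. = FALSE)
    v <- v[-seq_len(drop)]; ts <- ts[-seq_len(drop)]
  }
  n_days <- length(v) %/% 24L
  extra <- length(v) - n_days * 24L
  if (extra > 0L) {
    warning("trimming ", extra, " trailing sample(s) of a partial day",
            call. = FALSE)
    v <- v[seq_len(n_days * 24L)]; ts <- ts[seq_len(n_days * 24L)]
  }
  if (n_days < 2L)
    stop("need at least 2 complete days (got ", n_days, ")", call. = FALSE)
  m <- matrix(v, nrow = n_days, ncol = 24L, byrow = TRUE)
  structure(
    list(matrix = m,
         day_labels = as.Date(ts[seq(1L, by = 24L, length.out = n_days)],
                              tz = "UTC"),
         hour_labels = 0:23, term = series$term),
    class = "folded_days")
}

#' @export
print.folded_days <- function(x, ...) {
  cat(sprintf("<folded_days> term='%s'  %d days x 24 hours\n",
              x$term, nrow(x$matrix)))
  invisible(x)
}

#' Mean diurnal profile and peak-trough difference
#'
#' Column-wise arithmetic mean of the folded days: the average signal at
#' each clock hour. The peak (trough) hour is the argmax (argmin), ties
#' broken by the earliest hour, and `pp_difference` is the peak mean minus
#' the trough mean. On series normalized to a 0--100 maximum this difference
#' is in percentage points (pp) of the normalization maximum, the effect
#' size used throughout.
#'
#' @param folded A `folded_days` object from [fold_days()].
#' @return An object of class `diurnal_profile`: `mean_by_hour` (named,
#'   hours 0--23), `peak_hour`, `trough_hour`, `pp_difference`, `term`.
#' @export
mean_profile <- function(folded) {
  stopifnot(inherits(folded, "folded_days"))
  if (nrow(folded$matrix) < 2L)
    stop("need at least 2 days for a mean profile", call. = FALSE)
  new_diurnal_profile(colMeans(folded$matrix), term = folded$term)
}

new_diurnal_profile <- function(mean_by_hour, term = NA_character_) {
  stopifnot(length(mean_by_hour) == 24L)
  mean_by_hour <- stats::setNames(as.numeric(mean_by_hour), 0:23)
  peak <- as.integer(which.max(mean_by_hour)) - 1L   # first maximum on ties
  trough <- as.integer(which.min(mean_by_hour)) - 1L
  structure(
    list(mean_by_hour = mean_by_hour,
         peak_hour = peak, trough_hour = trough,
         pp_difference = unname(mean_by_hour[peak + 1L] -
                                  mean_by_hour[trough + 1L]),
         term = term),
    class = "diurnal_profile")
}

#' @export
print.diurnal_profile <- function(x, ...) {
  cat(sprintf(
    "<diurnal_profile> term='%s'  max. at %d-%d, min. at %d-%d, difference %.1f pp\n",
    x$term, x$peak_hour, x$peak_hour + 1L, x$trough_hour, x$trough_hour + 1L,
    x$pp_difference))
  invisible(x)
}

#' @export
as.data.frame.diurnal_profile <- function(x, ...) {
  data.frame(hour = 0:23, mean_rsv = unname(x$mean_by_hour))
}
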