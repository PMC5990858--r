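#' Hourly query series
#'
#' Container for one query term's hourly relative-search-volume (RSV) time
#' series. Raw RSV values live on the 0--100 scale Google Trends reports
#' (100 = the busiest hour in the normalization window); reconstructed
#' series hold real-valued band-passed signals and may be negative when the
#' series mean has not been restored.
#'
#' @param term Query term label (single string).
#' @param timestamps `POSIXct` vector of hourly instants, strictly
#'   increasing. Gaps are tolerated at construction so that
#'   [validate_series()] can repair them; uniform 1-hour spacing is required
#'   by all downstream analysis.
#' @param values Numeric vector, same length as `timestamps`. Raw series
#'   must lie in \[0, 100\]; reconstructed series only need to be finite.
#' @param is_reconstructed Logical flag separating raw RSV from band-passed
#'   signal values.
#'
#' @return An object of class `hourly_series`: a list with elements `term`,
#'   `timestamps`, `values`, `is_reconstructed`.
#' @seealso [read_trends_csv()], [validate_series()], [reconstruct_series()]
#' @export
#' @examples
#' ts <- seq(as.POSIXct("2017-03-01 00:00", tz = "UTC"), by = "hour",
#'           length.out = 48)
#' s <- hourly_series("masennus", ts, rep(50, 48))
#' s
hourly_series <- function(term, timestamps, values, is_reconstructed = FALSE) {
  stopifnot(is.character(term), length(term) == 1L, nzchar(term))
  if (!inherits(timestamps, "POSIXct"))
    stop("`timestamps` must be POSIXct", call. = FALSE)
  if (length(timestamps) != length(values))
    stop("`timestamps` and `values` lengths differ", call. = FALSE)
  if (length(values) < 2L)
    stop("a series needs at least 2 observations", call. = FALSE)
  d <- diff(as.numeric(timestamps))
  if (any(d <= 0))
    stop("timestamps must be strictly increasing (duplicate or unordered ",
         "timestamps at positions ", paste(which(d <= 0) + 1L, collapse = ", "),
         ")", call. = FALSE)
  if (any(d %% 3600 != 0))
    stop("timestamps must fall on a 1-hour grid", call. = FALSE)
  values <- as.numeric(values)
  if (!all(is.finite(values)))
    stop("non-finite values in series '", term, "'", call. = FALSE)
  if (!is_reconstructed && (any(values < 0) || any(values > 100)))
    stop("raw RSV values must lie in [0, 100] (term '", term, "')",
         call. = FALSE)
  structure(
    list(term = term, timestamps = timestamps, values = values,
         is_reconstructed = isTRUE(is_reconstructed)),
    class = "hourly_series"
  )
}

#' @export
print.hourly_series <- function(x, ...) {
  cat(sprintf(
    "<hourly_series> term='%s'  n=%d  %s .. %s  %s\n",
    x$term, length(x$values),
    format(x$timestamps[1], "%Y-%m-%dT%H", tz = "UTC"),
    format(x$timestamps[length(x$timestamps)], "%Y-%m-%dT%H", tz = "UTC"),
    if (x$is_reconstructed) "reconstructed" else "raw RSV"))
  cat(sprintf("  values: min=%.4g  mean=%.4g  max=%.4g\n",
              min(x$values), mean(x$values), max(x$values)))
  invisible(x)
}

#' @export
length.hourly_series <- function(x) length(x$values)

#' @export
as.data.frame.hourly_series <- function(x, ...) {
  data.frame(timestamp = x$timestamps, term = x$term, value = x$values,
             stringsAsFactors = FALSE)
}

# hour-of-day (0-23) for each observation, from the clock labels
series_hours <- function(series) as.POSIXlt(series$timestamps, tz = "UTC")$hour

# TRUE when spacing is exactly one hour everywhere
is_uniform_hourly <- function(series) {
  all(diff(as.numeric(series$timestamps)) == 3600)
}

assert_uniform <- function(series) {
  if (!is_uniform_hourly(series))
    stop("series '", series$term, "' has gaps; run validate_series() first",
         call. = FALSE)
  invisible(series)
}
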