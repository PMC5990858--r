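#' Read a Google-Trends-style hourly CSV
#'
#' Parses the hourly export dialect: a UTF-8 CSV with a header row, the first
#' column an ISO-8601-like hourly timestamp (`"YYYY-MM-DDTHH"`,
#' `"YYYY-MM-DDTHH:MM"`, and space-separated variants are accepted) and one
#' column per query term. Raw cells are integers 0--100 or the literal
#' `"<1"`, which Google Trends uses for suppressed small values and which is
#' mapped to 0. A leading `#reconstructed=true` comment line marks files
#' written from band-passed signals; their values are real and unrestricted.
#'
#' @param path Path to the CSV file.
#' @param strict When `TRUE` (default) any departure from a uniform 1-hour
#'   grid is an error listing the gap locations; when `FALSE` a gapped
#'   series is returned for repair by [validate_series()].
#'
#' @return A named list of [hourly_series()], one per term column.
#' @seealso [write_trends_csv()], [stitch_weekly()]
#' @export
read_trends_csv <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  reconstructed <- grepl("^#\\s*reconstructed\\s*=\\s*true", first,
                         ignore.case = TRUE)
  df <- utils::read.csv(path, check.names = FALSE, comment.char = "#",
                        colClasses = "character", strip.white = TRUE)
  if (ncol(df) < 2L)
    stop("expected a timestamp column plus at least one term column",
         call. = FALSE)
  ts <- parse_hourly_timestamps(df[[1L]])
  terms <- names(df)[-1L]
  out <- vector("list", length(terms))
  names(out) <- terms
  for (j in seq_along(terms)) {
    raw <- df[[j + 1L]]
    raw[raw == "<1"] <- "0"
    v <- suppressWarnings(as.numeric(raw))
    if (anyNA(v))
      stop("unparseable value(s) for term '", terms[j], "' at row(s) ",
           paste(utils::head(which(is.na(v)), 5L), collapse = ", "),
           call. = FALSE)
    if (!reconstructed) {
      if (any(v < 0 | v > 100))
        stop("RSV outside [0,100] for term '", terms[j], "' at row(s) ",
             paste(utils::head(which(v < 0 | v > 100), 5L), collapse = ", "),
             call. = FALSE)
      if (any(v != round(v)))
        stop("non-integer raw RSV for term '", terms[j], "' at row(s) ",
             paste(utils::head(which(v != round(v)), 5L), collapse = ", "),
             call. = FALSE)
    }
    if (strict) {
      d <- diff(as.numeric(ts)) / 3600
      if (any(d != 1))
        stop("non-hourly spacing after row(s) ",
             paste(utils::head(which(d != 1), 10L), collapse = ", "),
             " (gaps of ", paste(utils::head(d[d != 1], 10L), collapse = ", "),
             " h)", call. = FALSE)
    }
    out[[j]] <- hourly_series(terms[j], ts, v,
                              is_reconstructed = reconstructed)
  }
  out
}

parse_hourly_timestamps <- function(x) {
  x <- trimws(x)
  # pad bare "YYYY-MM-DDTHH" to a full instant
  bare <- grepl("^\\d{4}-\\d{2}-\\d{2}[T ]\\d{1,2}$", x)
  x[bare] <- paste0(x[bare], ":00")
  x <- sub("T", " ", x, fixed = TRUE)
  ts <- rep(as.POSIXct(NA), length(x))
  for (fmt in c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M")) {
    miss <- is.na(ts)
    if (!any(miss)) break
    ts[miss] <- as.POSIXct(strptime(x[miss], fmt, tz = "UTC"))
  }
  attr(ts, "tzone") <- "UTC"
  if (anyNA(ts))
    stop("malformed timestamp at row(s) ",
         paste(utils::head(which(is.na(ts)), 5L), collapse = ", "),
         call. = FALSE)
  ts
}

#' Write hourly series in the Google-Trends-style CSV dialect
#'
#' All series must share a common timestamp grid. Raw series are written as
#' integers; if any series is reconstructed, values are written with 4
#' decimal places and a `#reconstructed=true` comment header line is
#' prepended so [read_trends_csv()] round-trips the file.
#'
#' @param series_list A single [hourly_series()] or a list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trends_csv <- function(series_list, path) {
  if (inherits(series_list, "hourly_series")) series_list <- list(series_list)
  stopifnot(length(series_list) >= 1L)
  ts0 <- series_list[[1L]]$timestamps
  for (s in series_list)
    if (!identical(as.numeric(s$timestamps), as.numeric(ts0)))
      stop("all series must share one timestamp grid", call. = FALSE)
  reconstructed <- any(vapply(series_list, `[[`, logical(1),
                              "is_reconstructed"))
  fmt <- if (reconstructed) function(v) sprintf("%.4f", v)
         else function(v) as.character(as.integer(round(v)))
  cols <- lapply(series_list, function(s) fmt(s$values))
  header <- c("timestamp", vapply(series_list, `[[`, character(1), "term"))
  lines <- c(
    if (reconstructed) "#reconstructed=true",
    paste(header, collapse = ","),
    do.call(paste, c(list(format(ts0, "%Y-%m-%dT%H", tz = "UTC")), cols,
                     sep = ","))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Stitch overlapping weekly downloads of one term onto a common scale
#'
#' Google Trends normalizes each download window separately, so weekly
#' exports of the same term are on incompatible relative scales. Consecutive
#' segments are rescaled onto the first segment's scale using the ratio of
#' their means over the shared (overlapping) hours, concatenated with
#' overlapping hours resolved in favor of the earlier segment, and the
#' stitched series is finally renormalized so its maximum is exactly 100.
#' Abutting segments (gap of zero hours, no shared hour) cannot be
#' cross-calibrated; each such segment is normalized to its own maximum and
#' a warning is recorded in the report.
#'
#' @param segments List of [hourly_series()] for one term, in any order.
#' @param tolerance Absolute RSV tolerance beyond which overlapping rescaled
#'   values are counted as conflicts (default 0.5, one integer rounding
#'   step).
#' @param quantize Round the stitched series to integers and clip to
#'   \[0, 100\] (default `FALSE`).
#'
#' @return A list with elements `series` (the stitched [hourly_series()])
#'   and `report` (class `stitch_report`: `segments_in`, `overlap_hours`,
#'   `rescale_factors`, `conflicts`, `warnings`).
#' @export
stitch_weekly <- function(segments, tolerance = 0.5, quantize = FALSE) {
  if (inherits(segments, "hourly_series")) segments <- list(segments)
  stopifnot(length(segments) >= 1L)
  term <- segments[[1L]]$term
  for (s in segments) {
    if (!inherits(s, "hourly_series")) stop("segments must be hourly_series")
    if (s$term != term)
      stop("segments mix terms '", term, "' and '", s$term, "'",
           call. = FALSE)
    assert_uniform(s)
  }
  ord <- order(vapply(segments, function(s) as.numeric(s$timestamps[1]),
                      numeric(1)))
  segments <- segments[ord]

  n_seg <- length(segments)
  factors <- rep(1, n_seg)
  overlap_hours <- integer(max(n_seg - 1L, 0L))
  conflicts <- 0L
  warn <- character(0)

  acc_ts <- as.numeric(segments[[1L]]$timestamps)
  acc_v <- segments[[1L]]$values
  for (i in seq_len(n_seg - 1L)) {
    nxt <- segments[[i + 1L]]
    nxt_ts <- as.numeric(nxt$timestamps)
    gap_h <- (nxt_ts[1] - acc_ts[length(acc_ts)]) / 3600 - 1
    shared <- intersect(acc_ts, nxt_ts)
    overlap_hours[i] <- length(shared)
    if (length(shared) == 0L) {
      if (gap_h > 0)
        stop("gap of ", gap_h, " h between segments ", i, " and ", i + 1L,
             call. = FALSE)
      # abutting: no shared hours to calibrate on
      warn <- c(warn, sprintf(
        "segments %d and %d abut without overlap; per-segment max normalization used",
        i, i + 1L))
      if (i == 1L) acc_v <- acc_v / max(acc_v) * 100
      factors[i + 1L] <- 100 / max(nxt$values)
      acc_ts <- c(acc_ts, nxt_ts)
      acc_v <- c(acc_v, nxt$values * factors[i + 1L])
    } else {
      m_prev <- mean(acc_v[match(shared, acc_ts)])
      m_next <- mean(nxt$values[match(shared, nxt_ts)])
      if (m_next == 0 || m_prev == 0)
        stop("degenerate overlap (mean zero) between segments ", i, " and ",
             i + 1L, ": cannot rescale", call. = FALSE)
      factors[i + 1L] <- m_prev / m_next
      rescaled <- nxt$values * factors[i + 1L]
      conflicts <- conflicts + sum(
        abs(acc_v[match(shared, acc_ts)] - rescaled[match(shared, nxt_ts)]) >
          tolerance)
      keep <- !(nxt_ts %in% shared)  # earlier segment wins on overlap
      acc_ts <- c(acc_ts, nxt_ts[keep])
      acc_v <- c(acc_v, rescaled[keep])
    }
  }
  # global renormalization: the stitched month peaks at exactly 100
  acc_v <- acc_v / max(acc_v) * 100
  if (quantize) acc_v <- pmin(100, pmax(0, round(acc_v)))
  out <- hourly_series(term, as.POSIXct(acc_ts, tz = "UTC",
                                        origin = "1970-01-01"), acc_v)
  report <- structure(
    list(segments_in = n_seg, overlap_hours = overlap_hours,
         rescale_factors = factors, conflicts = conflicts, warnings = warn),
    class = "stitch_report")
  list(series = out, report = report)
}

#' @export
print.stitch_report <- function(x, ...) {
  cat(sprintf("<stitch_report> %d segment(s), %d conflict(s)\n",
              x$segments_in, x$conflicts))
  if (x$segments_in > 1L)
    cat("  overlap hours:", paste(x$overlap_hours, collapse = ", "),
        "\n  rescale factors:",
        paste(sprintf("%.4g", x$rescale_factors), collapse = ", "), "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Validate and repair an hourly series
#'
#' Enforces a uniform 1-hour grid. Interior gaps of at most `max_gap`
#' missing hours are filled by linear interpolation between the flanking
#' observations; longer gaps raise an error rather than being repaired.
#'
#' @param series An [hourly_series()].
#' @param max_gap Largest number of consecutive missing hours that may be
#'   interpolated (default 2).
#' @return The repaired series. Interpolated positions are recorded in the
#'   `"filled"` attribute (indices into the repaired series).
#' @export
validate_series <- function(series, max_gap = 2) {
  stopifnot(inherits(series, "hourly_series"))
  t_num <- as.numeric(series$timestamps)
  d <- diff(t_num) / 3600
  if (any(d == 0)) stop("duplicate timestamps", call. = FALSE)
  missing_h <- d - 1
  if (any(missing_h > max_gap)) {
    at <- which(missing_h > max_gap)[1L]
    stop("unrepairable gap of ", missing_h[at], " h after ",
         format(series$timestamps[at], "%Y-%m-%dT%H", tz = "UTC"),
         " (max_gap = ", max_gap, ")", call. = FALSE)
  }
  if (all(missing_h == 0)) return(series)
  full <- seq(t_num[1], t_num[length(t_num)], by = 3600)
  v <- stats::approx(t_num, series$values, xout = full)$y
  out <- hourly_series(series$term,
                       as.POSIXct(full, tz = "UTC", origin = "1970-01-01"),
                       v, is_reconstructed = series$is_reconstructed)
  attr(out, "filled") <- which(!(full %in% t_num))
  out
}
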