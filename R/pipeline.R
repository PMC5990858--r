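#' Run the full diurnal-rhythm pipeline
#'
#' Orchestrates the complete analysis for every query term: read (or
#' synthesize) hourly RSV series, validate, band-pass reconstruct over the
#' diurnal band, fold into days, compute the mean diurnal profile, build the
#' hourly Tukey-Kramer significance matrix (on the reconstructed,
#' mean-restored signal by default), and run the raw-RSV time-block
#' analysis. All per-term outputs plus a run manifest are written to
#' `out_dir` as plain CSV/JSON; identical config and seed give identical
#' files.
#'
#' @param config A named list (or path to a JSON file holding one) with
#'   elements: either `input` (one or more CSV paths for
#'   [read_trends_csv()]) or `synthetic` (arguments for
#'   [synthetic_config()]); optional `band` (default `c(4, 32)`), `alpha`
#'   (default 0.05), `block_unit` (`"hour"`/`"day"`), `raw_stats` (run the
#'   hourly statistics on raw instead of reconstructed values, default
#'   `FALSE`), `wavelet` (list of [cwt_morlet()] arguments), `seed`
#'   (overrides a synthetic config's seed).
#' @param out_dir Output directory, created if needed.
#' @param quiet Suppress per-stage log lines.
#' @return Invisibly, a list with per-term `profiles`, `matrices`, `blocks`
#'   and the `manifest`.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (!is.list(config)) stop("config must be a list or a JSON path",
                             call. = FALSE)
  band <- validate_band(config$band %||% c(4, 32))
  alpha <- config$alpha %||% 0.05
  block_unit <- config$block_unit %||% "hour"
  raw_stats <- isTRUE(config$raw_stats)
  wavelet_args <- config$wavelet %||% list()

  if (!is.null(config$synthetic)) {
    syn_args <- as.list(config$synthetic)
    if (!is.null(config$seed)) syn_args$seed <- config$seed
    syn <- do.call(synthetic_config, syn_args)
    series_list <- generate_series(syn)$series
  } else if (!is.null(config$input)) {
    paths <- as.character(config$input)
    if (length(paths) == 0L) stop("no input files given", call. = FALSE)
    series_list <- list()
    for (p in paths)
      for (s in read_trends_csv(p)) {
        if (!is.null(series_list[[s$term]]))
          stop("term '", s$term, "' appears in multiple inputs; stitch ",
               "segments with stitch_weekly() first", call. = FALSE)
        series_list[[s$term]] <- s
      }
  } else {
    stop("config needs either `input` paths or a `synthetic` block",
         call. = FALSE)
  }

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(stage, term, note) {
    if (!quiet)
      message(jsonlite::toJSON(
        list(stage = stage, term = term, note = note), auto_unbox = TRUE))
  }

  profiles <- list(); matrices <- list(); blocks <- list()
  for (term in names(series_list)) {
    slug <- gsub("[^A-Za-z0-9_-]+", "_", term)
    s <- validate_series(series_list[[term]])
    log_stage("validate", term, sprintf("n=%d", length(s)))

    rec <- do.call(reconstruct_series,
                   c(list(series = s, band = band), wavelet_args))
    log_stage("reconstruct", term,
              sprintf("band=[%g,%g]", band[1], band[2]))

    folded <- fold_days(rec)
    prof <- mean_profile(folded)
    profiles[[term]] <- prof
    utils::write.csv(as.data.frame(prof),
                     file.path(out_dir, paste0("profile_", slug, ".csv")),
                     row.names = FALSE)
    log_stage("profile", term,
              sprintf("peak=%d trough=%d pp=%.2f", prof$peak_hour,
                      prof$trough_hour, prof$pp_difference))

    stat_folded <- if (raw_stats) fold_days(s) else folded
    sig <- tukey_kramer(stat_folded, alpha = alpha)
    matrices[[term]] <- sig
    utils::write.csv(as.data.frame(sig),
                     file.path(out_dir, paste0("sigmatrix_", slug, ".csv")),
                     row.names = FALSE)
    utils::write.csv(
      as.data.frame(1L * sig$greater),
      file.path(out_dir, paste0("sigmatrix_", slug, "_indicator.csv")),
      row.names = FALSE)
    log_stage("hourly_stats", term,
              sprintf("significant_pairs=%d", sum(sig$greater)))

    blk <- block_anova_posthoc(s, alpha = alpha, unit = block_unit)
    blocks[[term]] <- blk
    utils::write.csv(blk$summary,
                     file.path(out_dir, paste0("blocks_", slug, ".csv")),
                     row.names = FALSE)
    utils::write.csv(blk$comparisons,
                     file.path(out_dir,
                               paste0("block_comparisons_", slug, ".csv")),
                     row.names = FALSE)
    log_stage("blocks", term, sprintf("F=%.3g p=%.3g", blk$F, blk$p))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("diurnalseek")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    terms = names(series_list),
    n_values_total = sum(vapply(series_list, length, integer(1))),
    band = band, alpha = alpha, block_unit = block_unit,
    raw_stats = raw_stats,
    seed = config$seed %||% config$synthetic$seed %||% NA,
    summary = data.frame(
      term = names(series_list),
      peak_hour = vapply(profiles, `[[`, integer(1), "peak_hour"),
      trough_hour = vapply(profiles, `[[`, integer(1), "trough_hour"),
      pp_difference = vapply(profiles, `[[`, numeric(1), "pp_difference"),
      row.names = NULL))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(profiles = profiles, matrices = matrices, blocks = blocks,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
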