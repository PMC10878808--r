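#' Temperature-trace tables
#'
#' A *trace* is a tibble of 1-minute logger records with columns
#' `logger_id`, `nest_id` (`NA` for ground-reference loggers deployed in
#' inactive nests), `site`, `timestamp` (POSIXct, timezone-naive local time
#' stored as UTC), and `temp` (degrees Celsius). All detection and covariate
#' functions in nestrec consume and return these tables, so several loggers
#' can be stacked in one tibble and processed with grouped pipelines.
#'
#' `validate_trace()` checks the invariants every downstream step relies on:
#' strictly increasing timestamps per logger, nominal 60 s spacing (larger
#' steps are *gaps*, which are kept explicit and never interpolated), and
#' temperatures inside a plausibility band.
#'
#' @param trace A trace tibble.
#' @param plausible_range Numeric length-2: allowed temperature band in
#'   degrees Celsius. Records outside it are dropped with a warning.
#' @return `validate_trace()` returns the trace, sorted, with duplicated
#'   timestamps collapsed to their first record and implausible records
#'   removed.
#' @export
validate_trace <- function(trace, plausible_range = c(-40, 60)) {
  required <- c("logger_id", "nest_id", "site", "timestamp", "temp")
  missing <- setdiff(required, names(trace))
  if (length(missing) > 0) {
    abort(paste0("trace is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (!inherits(trace$timestamp, "POSIXct")) {
    abort("trace$timestamp must be POSIXct")
  }
  trace <- dplyr::arrange(trace, logger_id, timestamp)

  bad <- !is.finite(trace$temp) |
    trace$temp < plausible_range[1] | trace$temp > plausible_range[2]
  if (any(bad)) {
    warn(sprintf("dropping %d record(s) with implausible or non-finite temperature", sum(bad)))
    trace <- trace[!bad, , drop = FALSE]
  }

  dup <- duplicated(trace[, c("logger_id", "timestamp")])
  if (any(dup)) {
    warn(sprintf("collapsing %d duplicated timestamp(s) to first occurrence", sum(dup)))
    trace <- trace[!dup, , drop = FALSE]
  }
  tibble::as_tibble(trace)
}

#' Gaps in a logger trace
#'
#' A gap is any step between consecutive records of one logger exceeding the
#' nominal 60 s sampling interval. Gaps terminate recess runs during
#' detection and are excluded from all statistics; they are never filled.
#'
#' @param trace A validated trace tibble.
#' @return Tibble with `logger_id`, `gap_start` (last record before the gap),
#'   `gap_end` (first record after), and `gap_minutes`.
#' @export
trace_gaps <- function(trace) {
  trace |>
    dplyr::group_by(logger_id) |>
    dplyr::reframe({
      dt <- diff(as.numeric(timestamp))
      i <- which(dt > 60)
      tibble::tibble(
        gap_start = timestamp[i],
        gap_end = timestamp[i + 1L],
        gap_minutes = dt[i] / 60 - 1
      )
    })
}

#' Read a logger CSV export
#'
#' Reads one thermologger export into a trace tibble. The canonical dialect
#' has columns `timestamp` (`YYYY-MM-DD HH:MM[:SS]`, local time) and `temp`;
#' other layouts (e.g. TinyTag CSV exports with renamed columns or other
#' datetime formats) are handled through the `dialect` list.
#'
#' Rows that fail to parse are dropped and counted; if more than half of the
#' rows are lost the file is considered unreadable and reading fails.
#'
#' @param path Path to the CSV file.
#' @param logger_id,nest_id,site Identifiers attached to every record.
#'   `nest_id = NA` marks a ground-reference logger.
#' @param dialect List with elements `timestamp_col`, `temp_col`,
#'   `datetime_format` (passed to [base::strptime()]), and `decimal_mark`.
#' @param plausible_range Passed to [validate_trace()].
#' @return A validated trace tibble with attribute `"n_dropped"`.
#' @export
read_logger_csv <- function(path, logger_id, nest_id = NA_character_,
                            site = "SITE",
                            dialect = csv_dialect(),
                            plausible_range = c(-40, 60)) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(.default = readr::col_character()),
                    locale = readr::locale(decimal_mark = dialect$decimal_mark)),
    error = function(e) abort(paste0("unparseable file ", path, ": ", conditionMessage(e)))
  )
  for (col in c(dialect$timestamp_col, dialect$temp_col)) {
    if (!col %in% names(raw)) {
      abort(paste0("file ", path, " lacks required column '", col, "'"))
    }
  }
  ts <- as.POSIXct(raw[[dialect$timestamp_col]],
                   format = dialect$datetime_format, tz = "UTC")
  tp <- suppressWarnings(as.numeric(
    sub(dialect$decimal_mark, ".", raw[[dialect$temp_col]], fixed = TRUE)))
  keep <- !is.na(ts) & !is.na(tp)
  n_dropped <- sum(!keep)
  if (nrow(raw) > 0 && n_dropped / nrow(raw) > 0.5) {
    abort(sprintf("more than 50%% of rows unparseable in %s (%d of %d)",
                  path, n_dropped, nrow(raw)))
  }
  if (n_dropped > 0) {
    warn(sprintf("%s: dropped %d unparseable row(s)", basename(path), n_dropped))
  }
  out <- tibble::tibble(
    logger_id = as.character(logger_id),
    nest_id = as.character(nest_id),
    site = as.character(site),
    timestamp = ts[keep],
    temp = tp[keep]
  )
  out <- validate_trace(out, plausible_range)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Canonical CSV dialect
#'
#' @param timestamp_col,temp_col Column names in the file.
#' @param datetime_format strptime-style format of the timestamp column.
#' @param decimal_mark Decimal separator used in the file.
#' @export
csv_dialect <- function(timestamp_col = "timestamp", temp_col = "temp",
                        datetime_format = "%Y-%m-%d %H:%M:%S",
                        decimal_mark = ".") {
  list(timestamp_col = timestamp_col, temp_col = temp_col,
       datetime_format = datetime_format, decimal_mark = decimal_mark)
}

#' Write a trace in the canonical CSV dialect
#'
#' Round-trips exactly with [read_logger_csv()] under the default dialect.
#'
#' @param trace A trace tibble (single logger).
#' @param path Output path.
#' @export
write_logger_csv <- function(trace, path) {
  out <- tibble::tibble(
    timestamp = format(trace$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
    temp = trace$temp
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Site-level ground temperature reference
#'
#' Combines the traces of ground loggers (deployed in inactive nests at one
#' site) into a single per-minute reference series by averaging, at each
#' minute, the loggers that cover it. Minutes covered by no logger remain
#' absent (gaps).
#'
#' @param traces Trace tibble of one or more ground loggers (`nest_id` `NA`).
#' @param site Site code to select (default: the single site present).
#' @param fun Per-minute combiner across loggers, default [mean()].
#' @return A trace-shaped tibble with `logger_id = "ground"`, one row per
#'   covered minute, carrying attribute `"n_loggers"`.
#' @export
build_ground_series <- function(traces, site = NULL, fun = mean) {
  if (nrow(traces) == 0) abort("no ground traces supplied")
  if (is.null(site)) {
    sites <- unique(traces$site)
    if (length(sites) != 1) abort("multiple sites present; supply `site`")
    site <- sites
  }
  traces <- dplyr::filter(traces, .data$site == !!site)
  if (nrow(traces) == 0) abort(paste0("no ground traces for site ", site))
  out <- traces |>
    dplyr::group_by(timestamp) |>
    dplyr::summarise(temp = fun(temp), .groups = "drop") |>
    dplyr::arrange(timestamp) |>
    dplyr::mutate(logger_id = "ground", nest_id = NA_character_, site = !!site) |>
    dplyr::select(logger_id, nest_id, site, timestamp, temp)
  attr(out, "n_loggers") <- length(unique(traces$logger_id))
  out
}

#' Daily summary of a ground series
#'
#' Mean and maximum temperature over the covered minutes of one local
#' calendar day, with the coverage fraction (covered minutes / 1440). A day
#' with no coverage yields `NA` statistics and `coverage = 0`.
#'
#' @param ground A ground series from [build_ground_series()].
#' @param days Optional vector of `Date`s; default, all days present.
#' @return Tibble with `date`, `mean_temp`, `max_temp`, `coverage`.
#' @export
daily_ground_stats <- function(ground, days = NULL) {
  gd <- ground |>
    dplyr::mutate(date = as.Date(timestamp, tz = "UTC")) |>
    dplyr::group_by(date) |>
    dplyr::summarise(
      mean_temp = mean(temp),
      max_temp = max(temp),
      coverage = dplyr::n() / 1440,
      .groups = "drop"
    )
  if (!is.null(days)) {
    gd <- dplyr::left_join(tibble::tibble(date = as.Date(days)), gd, by = "date") |>
      dplyr::mutate(coverage = dplyr::coalesce(coverage, 0))
  }
  gd
}
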