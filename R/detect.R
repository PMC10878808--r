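#' Detection parameters
#'
#' Tuning constants for recess detection and quality filtering. Defaults
#' follow the field protocol for sanderling nest thermologgers: a recess is
#' a drop of at least 4.5 degrees C below the daily maximum nest temperature
#' (or, under the legacy rule, 3 degrees C below the daily median), lasting
#' at least 3 minutes; records are retained only for nests monitored at
#' least 24 h and days whose maximum nest temperature reaches 37.5 degrees C
#' (incubation floor 36 degrees C plus the nominal 1.5 degrees C
#' nest-vs-ground offset, `ground_offset`).
#'
#' @param delta_max_drop Required drop below the daily maximum (degrees C).
#' @param delta_median_drop Required drop below the daily median for the
#'   legacy method (degrees C).
#' @param min_duration Minimum recess duration in minutes.
#' @param median_quality_floor Minimum daily median nest temperature for a
#'   day to count as a usable recording under the legacy method (degrees C).
#' @param daily_max_floor Minimum daily maximum temperature for a usable day
#'   (degrees C).
#' @param ground_offset Nominal nest-minus-ground temperature offset
#'   (degrees C); documentation constant relating the two floors.
#' @param min_monitoring Minimum monitored span per nest, hours.
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(delta_max_drop = 4.5,
                             delta_median_drop = 3,
                             min_duration = 3,
                             median_quality_floor = 36,
                             daily_max_floor = 37.5,
                             ground_offset = 1.5,
                             min_monitoring = 24) {
  p <- list(
    delta_max_drop = delta_max_drop,
    delta_median_drop = delta_median_drop,
    min_duration = min_duration,
    median_quality_floor = median_quality_floor,
    daily_max_floor = daily_max_floor,
    ground_offset = ground_offset,
    min_monitoring = min_monitoring
  )
  stopifnot(all(vapply(p, function(x) is.numeric(x) && x > 0, logical(1))),
            p$min_duration >= 1)
  structure(p, class = "detection_params")
}

# Detection for one logger's records (already sorted, deduplicated).
# Threshold is recomputed per local calendar day; a run that crosses
# midnight keeps the threshold of its onset day. Runs are maximal stretches
# of minutes *strictly below* threshold; gaps (> 60 s steps) terminate runs.
detect_one <- function(ts, temp, params, method) {
  n <- length(ts)
  out <- list()
  if (n == 0) return(out)
  tnum <- as.numeric(ts)
  segment <- cumsum(c(TRUE, diff(tnum) > 60))
  day <- as.Date(ts, tz = "UTC")
  days <- sort(unique(day))
  day_first <- match(days, day)

  thr_fun <- if (method == "max_drop") {
    function(x) max(x) - params$delta_max_drop
  } else {
    function(x) median(x) - params$delta_median_drop
  }
  thr <- vapply(days, function(d) thr_fun(temp[day == d]), numeric(1))

  claimed <- 0L # last index consumed by an accepted recess
  for (k in seq_along(days)) {
    i0 <- day_first[k]
    # extension window: onset day plus up to two following days
    iN <- n
    lim <- as.numeric(as.POSIXct(days[k], tz = "UTC")) + 3 * 86400
    while (iN > i0 && tnum[iN] >= lim) iN <- iN - 1L
    idx <- i0:iN
    below <- temp[idx] < thr[k]
    grp <- cumsum(c(TRUE, diff(segment[idx]) != 0 | diff(below) != 0))
    runs <- split(idx, grp)
    for (run in runs) {
      a <- run[1]
      if (day[a] != days[k]) break # later-day onsets handled on their own day
      if (!below[a - i0 + 1L] || a <= claimed) next
      L <- length(run)
      if (L >= params$min_duration) {
        out[[length(out) + 1L]] <- list(onset = ts[a], duration = L)
        claimed <- run[L]
      }
    }
  }
  out
}

#' Detect incubation recesses in nest temperature traces
#'
#' Segments each nest trace into incubation and recess bouts. For every
#' local calendar day a detection threshold is computed from the nest trace
#' itself: daily maximum minus `delta_max_drop` (`method = "max_drop"`, the
#' default) or daily median minus `delta_median_drop` (`method =
#' "median_drop"`, the legacy rule that underestimates extended recesses).
#' A recess is a maximal run of minutes strictly below threshold lasting at
#' least `min_duration` minutes. Runs crossing midnight keep the threshold
#' of their onset day and are reported as a single recess; gaps in the
#' record terminate runs.
#'
#' Nests whose monitored span is below `min_monitoring` hours contribute no
#' recesses and are listed in the `"flagged_short"` attribute.
#'
#' @param trace A validated trace tibble (one or more nest loggers).
#' @param params A [detection_params()] list.
#' @param method `"max_drop"` or `"median_drop"`.
#' @return Tibble with one row per recess: `recess_id`, `nest_id`,
#'   `logger_id`, `onset`, `end`, `duration` (minutes), `method`,
#'   `day_of_onset`, `is_capture_artifact`.
#' @export
detect_recesses <- function(trace, params = detection_params(),
                            method = c("max_drop", "median_drop")) {
  method <- match.arg(method)
  flagged <- character(0)
  res <- trace |>
    dplyr::group_by(logger_id, nest_id) |>
    dplyr::group_map(function(df, key) {
      hours <- (as.numeric(max(df$timestamp)) - as.numeric(min(df$timestamp)) + 60) / 3600
      if (hours < params$min_monitoring) {
        flagged <<- c(flagged, key$nest_id)
        return(NULL)
      }
      hits <- detect_one(df$timestamp, df$temp, params, method)
      if (length(hits) == 0) return(NULL)
      tibble::tibble(
        nest_id = key$nest_id,
        logger_id = key$logger_id,
        onset = as.POSIXct(vapply(hits, function(h) as.numeric(h$onset), numeric(1)),
                           origin = "1970-01-01", tz = "UTC"),
        duration = vapply(hits, function(h) h$duration, numeric(1))
      )
    }) |>
    purrr::list_rbind()
  if (nrow(res) == 0) {
    res <- tibble::tibble(nest_id = character(), logger_id = character(),
                          onset = as.POSIXct(character(), tz = "UTC"),
                          duration = numeric())
  }
  res <- res |>
    dplyr::arrange(nest_id, onset) |>
    dplyr::mutate(
      end = onset + duration * 60,
      method = method,
      day_of_onset = as.Date(onset, tz = "UTC"),
      is_capture_artifact = FALSE,
      recess_id = paste0(nest_id, "_", format(onset, "%Y%m%d%H%M"))
    ) |>
    dplyr::select(recess_id, nest_id, logger_id, onset, end, duration,
                  method, day_of_onset, is_capture_artifact)
  attr(res, "flagged_short") <- unique(flagged)
  res
}

# Per-day minute portions of recesses, splitting at local midnight so that
# daily totals never exceed 1440 and minutes are conserved.
recess_day_portions <- function(recesses) {
  if (nrow(recesses) == 0) {
    return(tibble::tibble(recess_id = character(), nest_id = character(),
                          date = as.Date(character()), minutes = numeric()))
  }
  purrr::pmap(
    list(recesses$recess_id, recesses$nest_id,
         as.numeric(recesses$onset), as.numeric(recesses$end)),
    function(rid, nid, a, b) {
      d0 <- as.Date(as.POSIXct(a, origin = "1970-01-01", tz = "UTC"), tz = "UTC")
      d1 <- as.Date(as.POSIXct(b - 60, origin = "1970-01-01", tz = "UTC"), tz = "UTC")
      ds <- seq(d0, d1, by = "day")
      lo <- as.numeric(as.POSIXct(ds, tz = "UTC"))
      hi <- lo + 86400
      tibble::tibble(recess_id = rid, nest_id = nid, date = ds,
                     minutes = (pmin(b, hi) - pmax(a, lo)) / 60)
    }
  ) |>
    purrr::list_rbind()
}

#' Total daily duration of recesses (TDR)
#'
#' Sums recess minutes within each local calendar nest-day. A recess that
#' crosses midnight contributes to each day only the minutes falling inside
#' it, so the per-nest sum of TDR equals the total detected recess minutes
#' and no day exceeds 1440.
#'
#' @param recesses A recess tibble from [detect_recesses()].
#' @return Tibble `nest_id`, `date`, `tdr` (minutes), `n_recesses` (recesses
#'   with onset on that day), `n_extended` (if a `class` column is present).
#' @export
compute_tdr <- function(recesses) {
  portions <- recess_day_portions(recesses) |>
    dplyr::group_by(nest_id, date) |>
    dplyr::summarise(tdr = sum(minutes), .groups = "drop")
  onsets <- recesses |>
    dplyr::group_by(nest_id, date = day_of_onset) |>
    dplyr::summarise(
      n_recesses = dplyr::n(),
      n_extended = if ("class" %in% names(recesses))
        sum(class == "extended") else NA_integer_,
      .groups = "drop"
    )
  dplyr::full_join(portions, onsets, by = c("nest_id", "date")) |>
    dplyr::mutate(
      tdr = dplyr::coalesce(tdr, 0),
      n_recesses = dplyr::coalesce(n_recesses, 0L)
    ) |>
    dplyr::arrange(nest_id, date)
}

#' Per-nest-day trace and recess summary
#'
#' Builds the nest-day table used by the quality filters and the TDR
#' models: daily maximum and median nest temperature, record coverage,
#' monitored hours per nest, TDR and recess counts.
#'
#' @param trace Nest trace tibble.
#' @param recesses Recess tibble for the same nests (possibly classified).
#' @return Tibble keyed by `nest_id`, `date`.
#' @export
nest_day_summary <- function(trace, recesses) {
  day_stats <- trace |>
    dplyr::mutate(date = as.Date(timestamp, tz = "UTC")) |>
    dplyr::group_by(nest_id, date) |>
    dplyr::summarise(
      daily_max_temp = max(temp),
      daily_median_temp = median(temp),
      coverage_minutes = dplyr::n(),
      .groups = "drop"
    )
  monitored <- trace |>
    dplyr::group_by(nest_id) |>
    dplyr::summarise(
      monitored_hours = (as.numeric(max(timestamp)) - as.numeric(min(timestamp)) + 60) / 3600,
      .groups = "drop")
  tdr <- compute_tdr(recesses)
  day_stats |>
    dplyr::left_join(monitored, by = "nest_id") |>
    dplyr::left_join(tdr, by = c("nest_id", "date")) |>
    dplyr::mutate(
      tdr = dplyr::coalesce(tdr, 0),
      n_recesses = dplyr::coalesce(n_recesses, 0L)
    )
}

#' Quality filtering of nest-days
#'
#' Applies the record-quality rules: nests monitored under
#' `min_monitoring` hours are excluded (`short_monitoring`); days whose
#' maximum nest temperature stays below `daily_max_floor` are excluded
#' (`daily_max_below_floor`); under the legacy median method, days with
#' median nest temperature at or below `median_quality_floor` are excluded
#' (`median_below_floor`); days listed in `manual_exclusions` are excluded
#' (`manual_erratic`). Every row is annotated, none silently dropped.
#'
#' @param nest_days Tibble from [nest_day_summary()].
#' @param params A [detection_params()] list.
#' @param manual_exclusions Optional tibble `nest_id`, `date` of days judged
#'   erratic on inspection.
#' @param method Detection method the days will feed; selects which floor
#'   applies.
#' @return `nest_days` with `quality_pass` and `excluded_reason` columns.
#' @export
apply_quality_filters <- function(nest_days, params = detection_params(),
                                  manual_exclusions = NULL,
                                  method = c("max_drop", "median_drop")) {
  method <- match.arg(method)
  manual <- if (is.null(manual_exclusions)) {
    tibble::tibble(nest_id = character(), date = as.Date(character()))
  } else {
    dplyr::mutate(manual_exclusions, date = as.Date(date))
  }
  nest_days |>
    dplyr::mutate(
      .manual = paste(nest_id, date) %in% paste(manual$nest_id, manual$date),
      excluded_reason = dplyr::case_when(
        monitored_hours < params$min_monitoring ~ "short_monitoring",
        method == "max_drop" & daily_max_temp < params$daily_max_floor ~
          "daily_max_below_floor",
        method == "median_drop" & daily_median_temp <= params$median_quality_floor ~
          "median_below_floor",
        .manual ~ "manual_erratic",
        TRUE ~ NA_character_
      ),
      quality_pass = is.na(excluded_reason)
    ) |>
    dplyr::select(-".manual")
}

#' Flag recesses overlapping capture events
#'
#' Recesses overlapping a known capture of the incubating bird are
#' behavioural artifacts; this marks them so [filter_recesses()] can drop
#' them with an explicit reason.
#'
#' @param recesses Recess tibble.
#' @param captures Tibble `nest_id`, `datetime` of capture events.
#' @export
flag_captures <- function(recesses, captures = NULL) {
  if (is.null(captures) || nrow(recesses) == 0 || nrow(captures) == 0) {
    return(recesses)
  }
  hit <- purrr::pmap_lgl(
    list(recesses$nest_id, as.numeric(recesses$onset), as.numeric(recesses$end)),
    function(nid, a, b) {
      any(captures$nest_id == nid &
            as.numeric(captures$datetime) >= a &
            as.numeric(captures$datetime) < b)
    }
  )
  dplyr::mutate(recesses, is_capture_artifact = is_capture_artifact | hit)
}

#' Restrict recesses to quality-passing nest-days
#'
#' Drops recesses whose onset day failed quality filtering and
#' capture-flagged recesses, returning the kept table plus an exclusion
#' report in attribute `"exclusions"` (reason-coded counts per rule so
#' `records_in = records_out + excluded`).
#'
#' @param recesses Recess tibble (after [flag_captures()] if applicable).
#' @param nest_days Annotated tibble from [apply_quality_filters()].
#' @export
filter_recesses <- function(recesses, nest_days) {
  bad_days <- nest_days |>
    dplyr::filter(!quality_pass) |>
    dplyr::select(nest_id, date, excluded_reason)
  joined <- recesses |>
    dplyr::left_join(bad_days, by = c("nest_id", "day_of_onset" = "date")) |>
    dplyr::mutate(excluded_reason = dplyr::if_else(
      is_capture_artifact, "capture_artifact", excluded_reason))
  kept <- joined |>
    dplyr::filter(is.na(excluded_reason)) |>
    dplyr::select(-excluded_reason)
  report <- joined |>
    dplyr::filter(!is.na(excluded_reason)) |>
    dplyr::count(excluded_reason, name = "n_excluded")
  attr(kept, "exclusions") <- report
  kept
}

#' Concordance of the max-drop and legacy median-drop methods
#'
#' Runs both detection rules on the same traces, applies each method's own
#' day-quality rule, and matches the resulting recesses one-to-one by
#' interval overlap (greedy on overlap fraction). The comparison documents
#' that the two rules agree on short recesses while the median rule loses
#' extended recesses: a long absence depresses the daily median below the
#' usable-recording floor, discarding the day under the legacy protocol.
#'
#' @param trace Nest trace tibble.
#' @param params A [detection_params()] list.
#' @return List with `matches` (tibble of max-drop recesses, matched
#'   median-drop recess id and overlap fraction), `unmatched_median`
#'   (median-drop recesses with no max-drop partner), and both raw tables.
#' @export
compare_methods <- function(trace, params = detection_params()) {
  run <- function(method) {
    r <- detect_recesses(trace, params, method)
    nd <- apply_quality_filters(nest_day_summary(trace, r), params, method = method)
    filter_recesses(r, nd)
  }
  rmax <- run("max_drop")
  rmed <- run("median_drop")
  if (nrow(rmax) == 0) {
    return(list(matches = tibble::tibble(), unmatched_median = rmed,
                max_drop = rmax, median_drop = rmed))
  }
  used <- rep(FALSE, nrow(rmed))
  match_id <- rep(NA_character_, nrow(rmax))
  overlap <- rep(0, nrow(rmax))
  for (i in seq_len(nrow(rmax))) {
    same <- which(!used & rmed$nest_id == rmax$nest_id[i])
    if (length(same) == 0) next
    inter <- pmin(as.numeric(rmed$end[same]), as.numeric(rmax$end[i])) -
      pmax(as.numeric(rmed$onset[same]), as.numeric(rmax$onset[i]))
    uni <- pmax(as.numeric(rmed$end[same]), as.numeric(rmax$end[i])) -
      pmin(as.numeric(rmed$onset[same]), as.numeric(rmax$onset[i]))
    frac <- pmax(inter, 0) / uni
    j <- which.max(frac)
    if (frac[j] > 0) {
      match_id[i] <- rmed$recess_id[same[j]]
      overlap[i] <- frac[j]
      used[same[j]] <- TRUE
    }
  }
  matches <- rmax |>
    dplyr::mutate(matched_median_id = match_id, overlap_fraction = overlap,
                  matched = !is.na(match_id))
  list(matches = matches,
       unmatched_median = rmed[!used, , drop = FALSE],
       max_drop = rmax, median_drop = rmed)
}
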