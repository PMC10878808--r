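#' Pipeline run configuration
#'
#' Bundles every setting of a full analysis run; together with `seed` it
#' determines all stochastic outputs. Either simulate a study
#' (`simulate = TRUE`) or point `input_dir` at a study bundle on disk (see
#' [read_study_bundle()]).
#'
#' @param seed Integer seed governing simulation and bootstrap.
#' @param simulate Generate the inputs with [simulate_study()].
#' @param input_dir Bundle directory when `simulate = FALSE`.
#' @param sim A [sim_params()] list.
#' @param detection A [detection_params()] list.
#' @param method Detection method.
#' @param n_boot Bootstrap resamples for the antimode CI.
#' @param windows Pre-recess temperature windows (hours).
#' @param alpha Significance level for interaction probing.
#' @param manual_exclusions,captures Optional exclusion tables (see
#'   [apply_quality_filters()], [flag_captures()]).
#' @param out_dir Optional directory for JSON/CSV artifacts.
#' @export
run_config <- function(seed = 1, simulate = TRUE, input_dir = NULL,
                       sim = sim_params(), detection = detection_params(),
                       method = "max_drop", n_boot = 1000,
                       windows = c(1, 2, 6, 12, 24), alpha = 0.05,
                       manual_exclusions = NULL, captures = NULL,
                       out_dir = NULL) {
  structure(as.list(environment()), class = "run_config")
}

# drop fixed-effect terms that are constant on the modelling data
drop_constant_terms <- function(data, fixed) {
  keep <- vapply(fixed, function(v) {
    x <- data[[v]]
    length(unique(x[!is.na(x)])) > 1
  }, logical(1))
  fixed[keep]
}

fit_family_with_selection <- function(data, response, fixed, windows, family,
                                      random = "nest_id", alpha = 0.05) {
  fixed <- drop_constant_terms(data, fixed)
  opt <- optimize_time_window(data, response, fixed, windows = windows,
                              family = family, random = random)
  w <- opt$best_window
  tc <- paste0("temp_", w, "h")
  fit_without <- opt$fits[[paste0(w, "h")]]
  sel <- NULL
  jn <- NULL
  if ("body_condition" %in% fixed) {
    fit_with <- tryCatch(
      fit_mixed_model(fit_without$data_raw, response, c(fixed, tc),
                      interaction = c(tc, "body_condition"),
                      random = random, family = family),
      error = function(e) NULL)
    if (!is.null(fit_with)) {
      sel <- select_interaction_model(fit_with, fit_without)
      if (!is.null(fit_with$interaction)) {
        jn <- tryCatch(
          simple_slopes_jn(fit_with, tc, "body_condition", alpha = alpha),
          error = function(e) NULL)
      }
    }
  }
  list(window = opt, fit = if (is.null(sel)) fit_without else sel$chosen,
       selection = sel, jn = jn)
}

#' Run the full incubation-recess analysis pipeline
#'
#' Executes every stage on one configured input: ingest or simulate,
#' detect recesses (daily max-drop rule), quality-filter nest-days,
#' estimate and bootstrap the short/extended antimode threshold, classify,
#' build covariates, then fit the model roster -- extended-recess
#' occurrence GLMM with AIC window optimization, extended- and
#' short-duration LMMs, and TDR LMMs for days with and without extended
#' recesses -- each with temperature-by-condition interaction selection by
#' marginal R-squared and Johnson-Neyman probing where an interaction is
#' present. Each stage logs record counts into the run ledger; the
#' consolidated report is returned (and written as JSON when
#' `config$out_dir` is set).
#'
#' @param config A [run_config()].
#' @return A list of class `recess_report`.
#' @export
run_pipeline <- function(config = run_config()) {
  ledger <- list()
  note <- function(stage, n_in, n_out, detail = NULL) {
    ledger[[length(ledger) + 1L]] <<- tibble::tibble(
      stage = stage, records_in = n_in, records_out = n_out,
      detail = detail %||% NA_character_)
  }

  study <- if (config$simulate) {
    simulate_study(config$sim, seed = config$seed)
  } else {
    if (is.null(config$input_dir)) abort("simulate = FALSE needs input_dir")
    read_study_bundle(config$input_dir)
  }
  note("input", NA, nrow(study$nest_traces), "nest trace minutes")

  recesses <- detect_recesses(study$nest_traces, config$detection, config$method)
  recesses <- flag_captures(recesses, config$captures)
  note("detect", nrow(study$nest_traces), nrow(recesses), "recesses detected")

  nest_days <- nest_day_summary(study$nest_traces, recesses) |>
    apply_quality_filters(config$detection, config$manual_exclusions,
                          method = config$method)
  kept <- filter_recesses(recesses, nest_days)
  note("quality_filter", nrow(recesses), nrow(kept),
       paste0("excluded: ", nrow(recesses) - nrow(kept)))

  threshold <- bootstrap_threshold(kept$duration, n_boot = config$n_boot,
                                   seed = config$seed + 1L)
  classified <- classify_recesses(kept, threshold)
  nest_days <- nest_day_summary(study$nest_traces, classified) |>
    apply_quality_filters(config$detection, config$manual_exclusions,
                          method = config$method)
  note("classify", nrow(kept), nrow(classified),
       sprintf("antimode %.1f min", threshold$antimode))

  smi <- scaled_mass_index(study$morphometrics)
  condition <- dplyr::distinct(smi[, c("nest_id", "smi")], nest_id, .keep_all = TRUE)
  covariates <- build_recess_covariates(classified, study$ground,
                                        study$metadata, condition,
                                        windows = config$windows)
  note("covariates", nrow(classified), sum(complete.cases(
    covariates[, paste0("temp_", config$windows, "h")])),
    "recesses with full window coverage")

  base_fixed <- c("body_condition", "sex", "incubation_date", "period", "nest_type")
  models <- list()
  models$occurrence <- tryCatch(
    fit_family_with_selection(covariates, "extended", base_fixed,
                              config$windows, "binomial", alpha = config$alpha),
    error = function(e) {warn(paste("occurrence model:", conditionMessage(e))); NULL})
  ext_cov <- dplyr::filter(covariates, class == "extended")
  dur_fixed <- setdiff(base_fixed, "period")
  models$duration_extended <- if (nrow(ext_cov) >= 30 &&
                                  length(unique(ext_cov$nest_id)) >= 5) {
    tryCatch(
      fit_family_with_selection(ext_cov, "duration", dur_fixed,
                                config$windows, "gaussian", alpha = config$alpha),
      error = function(e) {warn(paste("extended-duration model:",
                                      conditionMessage(e))); NULL})
  }
  short_cov <- dplyr::filter(covariates, class == "short")
  models$duration_short <- tryCatch(
    fit_family_with_selection(short_cov, "duration", dur_fixed,
                              config$windows, "gaussian", alpha = config$alpha),
    error = function(e) {warn(paste("short-duration model:",
                                    conditionMessage(e))); NULL})

  # nest-day table for the TDR models
  daily_ground <- daily_ground_stats(study$ground)
  tdr_data <- nest_days |>
    dplyr::filter(quality_pass) |>
    dplyr::left_join(daily_ground[, c("date", "mean_temp")], by = "date") |>
    dplyr::left_join(study$metadata[, c("nest_id", "incubation_start",
                                        "sex", "strategy")], by = "nest_id") |>
    dplyr::left_join(condition, by = "nest_id") |>
    dplyr::mutate(
      body_condition = smi,
      nest_type = ifelse(strategy == "swap", "swap", "uni"),
      incubation_date = as.numeric(date - as.Date(incubation_start)),
      temp_daily = mean_temp,
      n_extended = dplyr::coalesce(n_extended, 0L)
    )
  tdr_fixed <- c("temp_daily", "body_condition", "sex", "incubation_date", "nest_type")
  fit_tdr <- function(df) {
    fixed <- drop_constant_terms(df, tdr_fixed)
    f_wo <- fit_mixed_model(df, "tdr", fixed, family = "gaussian")
    f_wi <- if (all(c("temp_daily", "body_condition") %in% fixed)) {
      tryCatch(fit_mixed_model(df, "tdr", fixed,
                               interaction = c("temp_daily", "body_condition"),
                               family = "gaussian"),
               error = function(e) NULL)
    }
    sel <- if (!is.null(f_wi)) select_interaction_model(f_wi, f_wo)
    jn <- if (!is.null(f_wi)) {
      tryCatch(simple_slopes_jn(f_wi, "temp_daily", "body_condition",
                                alpha = config$alpha),
               error = function(e) NULL)
    }
    list(fit = if (is.null(sel)) f_wo else sel$chosen, selection = sel, jn = jn)
  }
  with_ext <- dplyr::filter(tdr_data, n_extended > 0)
  without_ext <- dplyr::filter(tdr_data, n_extended == 0)
  models$tdr_with_extended <- if (nrow(with_ext) >= 20 &&
                                  length(unique(with_ext$nest_id)) >= 5) {
    tryCatch(fit_tdr(with_ext), error = function(e) {
      warn(paste("TDR (with extended) model:", conditionMessage(e))); NULL})
  }
  models$tdr_without_extended <- if (nrow(without_ext) >= 20 &&
                                     length(unique(without_ext$nest_id)) >= 5) {
    tryCatch(fit_tdr(without_ext), error = function(e) {
      warn(paste("TDR (without extended) model:", conditionMessage(e))); NULL})
  }

  summary_tbl <- summarize_recesses(classified, nest_days, study$metadata)
  report <- structure(list(
    config = config, threshold = threshold,
    recesses = classified, nest_days = nest_days, covariates = covariates,
    tdr_data = tdr_data, models = models, summary = summary_tbl,
    ledger = purrr::list_rbind(ledger), truth = study$truth
  ), class = "recess_report")

  if (!is.null(config$out_dir)) {
    write_report(report, config$out_dir)
  }
  report
}

#' @export
print.recess_report <- function(x, ...) {
  cat("Incubation recess analysis report\n")
  print(x$threshold)
  print(x$summary$by_strategy)
  fitted <- names(x$models)[!vapply(x$models, is.null, logical(1))]
  cat("models fitted:", paste(fitted, collapse = ", "), "\n")
  invisible(x)
}

#' Descriptive recess summaries
#'
#' Per-strategy recess rates and duration statistics, plus annual
#' extended-recess shares (count and duration), mirroring the descriptive
#' tables of a field study.
#'
#' @param recesses Classified recess tibble.
#' @param nest_days Quality-annotated nest-day tibble.
#' @param metadata Nest metadata (for strategy and year).
#' @return List of tibbles `by_strategy`, `by_year`, `durations`.
#' @export
summarize_recesses <- function(recesses, nest_days, metadata = NULL) {
  if (nrow(recesses) == 0) {
    empty <- tibble::tibble()
    return(list(by_strategy = empty, by_year = empty, durations = empty))
  }
  r <- recesses
  if (!is.null(metadata)) {
    mcols <- intersect(c("nest_id", "strategy", "year"), names(metadata))
    r <- dplyr::left_join(r, metadata[, mcols], by = "nest_id")
  }
  if (!"strategy" %in% names(r)) r$strategy <- "unknown"
  if (!"class" %in% names(r)) r$class <- factor("short", c("short", "extended"))
  days_per_nest <- nest_days |>
    dplyr::filter(quality_pass) |>
    dplyr::count(nest_id, name = "n_days")
  by_strategy <- r |>
    dplyr::left_join(days_per_nest, by = "nest_id") |>
    dplyr::group_by(strategy) |>
    dplyr::summarise(
      n_nests = dplyr::n_distinct(nest_id),
      n_recesses = dplyr::n(),
      n_extended = sum(class == "extended"),
      prop_extended = mean(class == "extended"),
      recesses_per_day = dplyr::n() /
        sum(days_per_nest$n_days[days_per_nest$nest_id %in% unique(nest_id)]),
      .groups = "drop"
    )
  by_year <- if ("year" %in% names(r)) {
    r |>
      dplyr::group_by(year) |>
      dplyr::summarise(
        n_recesses = dplyr::n(),
        n_extended = sum(class == "extended"),
        prop_extended_count = mean(class == "extended"),
        prop_extended_duration = sum(duration[class == "extended"]) / sum(duration),
        .groups = "drop"
      )
  } else tibble::tibble()
  durations <- r |>
    dplyr::group_by(class) |>
    dplyr::summarise(
      n = dplyr::n(), min = min(duration), mean = mean(duration),
      median = median(duration), max = max(duration), .groups = "drop"
    )
  list(by_strategy = by_strategy, by_year = by_year, durations = durations)
}

#' Write pipeline artifacts
#'
#' Writes the consolidated JSON report plus the stage tables (recesses,
#' nest-days, covariates) as CSV into `dir`.
#'
#' @param report A `recess_report`.
#' @param dir Output directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fit_json <- function(m) {
    if (is.null(m)) return(NULL)
    list(
      coefficients = tidy(m$fit),
      glance = glance(m$fit),
      window_table = if (!is.null(m$window)) m$window$table,
      best_window = if (!is.null(m$window)) m$window$best_window,
      interaction_selected = if (!is.null(m$selection)) m$selection$selected,
      jn = if (!is.null(m$jn)) list(slopes = m$jn$slopes, bounds = m$jn$jn)
    )
  }
  payload <- list(
    seed = report$config$seed,
    threshold = tidy(report$threshold),
    summary = report$summary,
    models = purrr::map(report$models, fit_json),
    ledger = report$ledger
  )
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       null = "null", force = TRUE, pretty = TRUE)
  readr::write_csv(report$recesses, file.path(dir, "recesses.csv"))
  readr::write_csv(report$nest_days, file.path(dir, "nest_days.csv"))
  readr::write_csv(report$covariates, file.path(dir, "covariates.csv"))
  invisible(dir)
}
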