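#' Scaled mass index of body condition
#'
#' Standardizes each bird's body mass to a common structural size. The
#' scaling exponent is the standardized major axis (SMA) slope of ln(mass)
#' on ln(tarsus), `b_SMA = b_OLS / r`, and each bird's mass is rescaled to
#' the reference tarsus length `L0`:
#' `SMI_i = mass_i * (L0 / tarsus_i)^b_SMA`. `L0` defaults to the arithmetic
#' mean tarsus of the sample; supply a published value to reproduce an
#' external index. SMI is in grams and is treated as a per-bird constant
#' (birds measured once during incubation).
#'
#' @param measurements Tibble with `mass` (g) and `tarsus` (mm) columns; any
#'   id columns are passed through.
#' @param ref_length Reference tarsus length `L0` in mm, or `NULL` for the
#'   sample mean.
#' @param mass_range Plausibility band for mass (g); violations error.
#' @return `measurements` with an `smi` column; attributes `b_sma`, `L0`,
#'   `r` (Pearson correlation of the log measurements).
#' @export
scaled_mass_index <- function(measurements, ref_length = NULL,
                              mass_range = c(30, 90)) {
  m <- measurements$mass
  l <- measurements$tarsus
  if (length(m) < 3) abort("need >= 3 birds to fit the SMA scaling exponent")
  if (any(!is.finite(m)) || any(!is.finite(l)) || any(l <= 0) || any(m <= 0)) {
    abort("mass and tarsus must be positive and finite")
  }
  if (any(m < mass_range[1] | m > mass_range[2])) {
    abort(sprintf("mass outside plausibility band [%g, %g] g",
                  mass_range[1], mass_range[2]))
  }
  lm_ <- log(m); ll <- log(l)
  r <- suppressWarnings(cor(lm_, ll))
  if (is.na(r) || r == 0) abort("scaling exponent undefined: cor(ln mass, ln tarsus) is 0 or NA")
  b_ols <- cov(lm_, ll) / var(ll)
  b_sma <- b_ols / r
  L0 <- ref_length %||% mean(l)
  out <- dplyr::mutate(measurements, smi = mass * (L0 / tarsus)^b_sma)
  attr(out, "b_sma") <- b_sma
  attr(out, "L0") <- L0
  attr(out, "r") <- r
  out
}

# Cumulative-sum index over a minute grid for fast window means with gaps.
ground_index <- function(ground) {
  t0 <- min(ground$timestamp)
  minutes <- as.integer(round((as.numeric(ground$timestamp) - as.numeric(t0)) / 60))
  n <- max(minutes) + 1L
  temp <- rep(NA_real_, n)
  temp[minutes + 1L] <- ground$temp
  covered <- !is.na(temp)
  list(
    origin = as.numeric(t0),
    cum_temp = cumsum(ifelse(covered, temp, 0)),
    cum_cov = cumsum(covered),
    n = n
  )
}

#' Mean ground temperature over a pre-onset window
#'
#' Average ground-level temperature over the half-open window
#' `[t0 - hours, t0)` ending at a recess onset (the onset minute itself is
#' excluded). Only covered minutes contribute; if coverage falls below
#' `min_coverage` of the window, the value is `NA` and the recess is later
#' dropped from models using that window.
#'
#' @param ground A ground series from [build_ground_series()].
#' @param t0 POSIXct vector of window end times (recess onsets).
#' @param hours Window length in hours (the analysis set is 1, 2, 6, 12, 24).
#' @param min_coverage Minimum covered fraction of the window.
#' @return Numeric vector, one mean per element of `t0`.
#' @export
window_mean_ground_temp <- function(ground, t0, hours, min_coverage = 0.5) {
  window_mean_gi(ground_index(ground), t0, hours, min_coverage)
}

# Core of window_mean_ground_temp on a precomputed ground_index(); used by
# the simulator too, where many windows are taken against one series.
window_mean_gi <- function(gi, t0, hours, min_coverage = 0.5) {
  w <- as.integer(hours * 60)
  # window minutes [e - w, e - 1] where e = minutes from origin of t0
  e <- floor((as.numeric(t0) - gi$origin) / 60)
  hi <- pmin(e, gi$n) # exclusive upper index (1-based cumsum positions)
  lo <- pmin(pmax(e - w, 0), gi$n)
  valid <- hi > lo
  cs <- function(v, i) ifelse(i > 0, v[pmax(i, 1)], 0)
  cov_n <- ifelse(valid, cs(gi$cum_cov, hi) - cs(gi$cum_cov, lo), 0)
  s <- ifelse(valid, cs(gi$cum_temp, hi) - cs(gi$cum_temp, lo), 0)
  out <- ifelse(cov_n >= min_coverage * w, s / cov_n, NA_real_)
  as.numeric(out)
}

#' Day/night period of a timestamp
#'
#' Sanderlings keep a circadian incubation rhythm under permanent Arctic
#' daylight: "night" is the quiet phase 17:00-09:00 local time (960 min),
#' "day" the active phase 09:00-17:00 (480 min). The 09:00 boundary belongs
#' to day, the 17:00 boundary to night.
#'
#' @param t POSIXct vector.
#' @return Factor with levels `day`, `night`.
#' @export
assign_period <- function(t) {
  lt <- as.POSIXlt(t, tz = "UTC")
  minute_of_day <- lt$hour * 60 + lt$min
  factor(ifelse(minute_of_day >= 17 * 60 | minute_of_day < 9 * 60,
                "night", "day"),
         levels = c("day", "night"))
}

#' Build the per-recess model covariate table
#'
#' Assembles, for each classified recess, the covariates entering the
#' occurrence and duration models: mean ground temperature over the 1, 2,
#' 6, 12 and 24 h pre-onset windows (`temp_1h` ... `temp_24h`), body
#' condition (SMI), sex, incubation date (days since the start of
#' incubation), day/night period of the onset, and nest type.
#'
#' @param recesses Classified recess tibble.
#' @param ground Ground series for the site.
#' @param metadata Nest metadata tibble with `nest_id`, `incubation_start`,
#'   `sex`, and `strategy` (or `nest_type`).
#' @param condition Tibble with `nest_id` and `smi` (one row per nest; from
#'   [scaled_mass_index()] joined to nests).
#' @param windows Window lengths in hours.
#' @param min_coverage Passed to [window_mean_ground_temp()].
#' @return Covariate tibble keyed by `recess_id`, with `extended` coded
#'   0/1 from `class` when present.
#' @export
build_recess_covariates <- function(recesses, ground, metadata, condition = NULL,
                                    windows = c(1, 2, 6, 12, 24),
                                    min_coverage = 0.5) {
  out <- recesses
  for (w in windows) {
    out[[paste0("temp_", w, "h")]] <-
      window_mean_ground_temp(ground, recesses$onset, w, min_coverage)
  }
  meta_cols <- intersect(c("nest_id", "incubation_start", "sex", "strategy",
                           "nest_type", "year", "site"), names(metadata))
  out <- dplyr::left_join(out, metadata[, meta_cols], by = "nest_id")
  if (!"nest_type" %in% names(out) && "strategy" %in% names(out)) {
    out$nest_type <- ifelse(out$strategy == "swap", "swap", "uni")
  }
  out$incubation_date <-
    as.numeric(as.Date(out$onset, tz = "UTC") - as.Date(out$incubation_start))
  out$period <- assign_period(out$onset)
  if (!is.null(condition)) {
    out <- dplyr::left_join(out, condition[, c("nest_id", "smi")], by = "nest_id")
    out <- dplyr::rename(out, body_condition = "smi")
  }
  if ("class" %in% names(out)) {
    out$extended <- as.integer(out$class == "extended")
  }
  tibble::as_tibble(out)
}
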