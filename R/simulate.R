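#' Synthetic-study generator parameters
#'
#' Defaults are calibrated to emulate the qualitative regime of uniparental
#' sanderling incubation in the high Arctic -- they are a test harness, not
#' field truth: an incubated-nest baseline near 38 degrees C; a diurnal
#' ground temperature (sinusoid peaking mid-afternoon plus slowly-varying
#' AR(1) weather) spanning roughly 0-15 degrees C; around 20-24 recesses
#' per nest-day, concentrated in the 09:00-17:00 active phase; a bimodal
#' lognormal duration mixture with modes near 7 and 340 min; extended-bout
#' probability ~2% at the mean temperature falling with warmer 12 h
#' pre-onset temperature (logistic slope ~ -0.22 per degree C, i.e. ~20%
#' lower odds per degree); and an extended-bout duration responding to the
#' 6 h pre-onset temperature with a temperature-by-body-condition
#' interaction (slope ~ -21 min/degree C for the poorest birds, ~0 for the
#' best).
#'
#' @param n_nests Number of nests.
#' @param days_per_nest Monitored days per nest.
#' @param t_incubation Incubated-nest baseline temperature, degrees C.
#' @param noise_sd Logger noise SD, degrees C.
#' @param ground_mean,ground_amp Diurnal sinusoid mean and amplitude,
#'   degrees C; daily peak at `ground_peak_hour`.
#' @param ground_ar1,ground_sd AR(1) coefficient (per minute) and
#'   stationary SD of the weather component.
#' @param n_ground_loggers Ground-reference loggers per site.
#' @param start_spread_days Nest monitoring starts are staggered uniformly
#'   over this many days, as field nests are initiated across the season.
#' @param cooling_tau Exponential time constant (minutes) of nest cooling
#'   toward ground temperature during a recess; rewarming on return is
#'   treated as immediate at 1-min resolution.
#' @param recess_hazard Per-minute recess initiation hazard during the
#'   day phase; multiplied by `night_rate_factor` 17:00-09:00.
#' @param night_rate_factor Hazard multiplier for the night phase.
#' @param short_dur_logmean,short_dur_logsd Lognormal short-bout duration
#'   (minutes, log scale).
#' @param ext_dur_logmean,ext_dur_logsd Lognormal core of the extended-bout
#'   duration.
#' @param occ_beta0,occ_betaT Logistic intercept and slope (per degree C of
#'   12 h pre-onset ground temperature, centred at `ground_mean`) for a
#'   bout being extended.
#' @param occ_re_sd Between-nest SD of the occurrence logit intercept.
#' @param dur_beta0,dur_betaT,dur_betaBC,dur_betaTxBC Additive shift
#'   (minutes) of extended-bout duration: intercept, per degree C of 6 h
#'   temperature, per gram of body condition, and their interaction
#'   (temperature and condition centred at `ground_mean` / `bc_mean`).
#' @param dur_re_sd Between-nest SD (minutes) of extended duration.
#' @param ext_min_duration Floor (minutes) of extended-bout duration.
#' @param min_duration Floor (minutes) of any bout.
#' @param bc_mean,bc_sd Body-condition (SMI, grams) distribution.
#' @param tarsus_mean,tarsus_sd,smi_exponent Morphometric generator: tarsus
#'   (mm) and the allometric exponent tying mass to condition.
#' @param site,year Labels stamped on the bundle.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_nests = 63, days_per_nest = 10,
                       t_incubation = 38, noise_sd = 0.3,
                       ground_mean = 10, ground_amp = 6,
                       ground_ar1 = 0.995, ground_sd = 3.5,
                       n_ground_loggers = 2, start_spread_days = 14,
                       cooling_tau = 1,
                       recess_hazard = 0.06, night_rate_factor = 0.15,
                       short_dur_logmean = log(7), short_dur_logsd = 0.9,
                       ext_dur_logmean = log(340), ext_dur_logsd = 0.3,
                       occ_beta0 = qlogis(0.02), occ_betaT = -0.22,
                       occ_re_sd = 0.4,
                       dur_beta0 = 0, dur_betaT = -10, dur_betaBC = -5,
                       dur_betaTxBC = 0.8, dur_re_sd = 30,
                       ext_min_duration = 121, min_duration = 3,
                       bc_mean = 55, bc_sd = 6,
                       tarsus_mean = 25.5, tarsus_sd = 0.8, smi_exponent = 2,
                       site = "SYN", year = 2019L) {
  p <- as.list(environment())
  stopifnot(p$cooling_tau > 0, p$noise_sd >= 0, p$ground_sd >= 0,
            p$min_duration >= 1)
  structure(p, class = "sim_params")
}

# stationary AR(1) path with given per-step coefficient and stationary SD
ar1_path <- function(n, phi, sd_stat) {
  if (sd_stat == 0 || n == 0) return(rep(0, n))
  innov_sd <- sd_stat * sqrt(1 - phi^2)
  as.numeric(stats::filter(rnorm(n, 0, innov_sd), phi, method = "recursive",
                           init = rnorm(1, 0, sd_stat)))
}

diurnal_cycle <- function(timestamps, mean, amp, peak_hour = 14) {
  lt <- as.POSIXlt(timestamps, tz = "UTC")
  mod <- lt$hour * 60 + lt$min
  mean + amp * cos(2 * pi * (mod - peak_hour * 60) / 1440)
}

#' Simulate a ground-reference temperature series
#'
#' Minute-resolution ground-level temperature: diurnal sinusoid (peak
#' mid-afternoon) plus AR(1) weather plus logger noise. Used both
#' standalone and inside [simulate_study()].
#'
#' @param params A [sim_params()] list.
#' @param n_days Days to simulate.
#' @param start POSIXct start (midnight local).
#' @param logger_id,site Identifiers for the returned trace.
#' @param weather Optional precomputed weather vector (one value per
#'   minute) shared across loggers of one site.
#' @param seed Optional seed.
#' @return A ground-logger trace tibble.
#' @export
simulate_ground <- function(params = sim_params(), n_days = 1,
                            start = as.POSIXct("2019-06-20 00:00:00", tz = "UTC"),
                            logger_id = "G1", site = params$site,
                            weather = NULL, seed = NULL) {
  stopifnot(n_days >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_days * 1440)
  ts <- start + 60 * (0:(n - 1L))
  w <- weather %||% ar1_path(n, params$ground_ar1, params$ground_sd)
  temp <- diurnal_cycle(ts, params$ground_mean, params$ground_amp) + w +
    rnorm(n, 0, params$noise_sd)
  tibble::tibble(logger_id = logger_id, nest_id = NA_character_, site = site,
                 timestamp = ts, temp = temp)
}

#' Simulate one nest trace with planted recesses
#'
#' Minute process for a single uniparental nest: during incubation the nest
#' reads `t_incubation` plus noise; recesses start with a per-minute hazard
#' (reduced 17:00-09:00), are extended with probability
#' `plogis(occ_beta0 + occ_betaT * (T12h - ground_mean) + re_occ)`, draw
#' their duration from the short or extended process (the extended mean
#' shifted linearly by the 6 h temperature, body condition and their
#' interaction), and during a recess the nest temperature relaxes
#' exponentially toward ground temperature with time constant
#' `cooling_tau`. Every planted bout is recorded as ground truth.
#'
#' @param params A [sim_params()] list.
#' @param ground Site ground series (from [build_ground_series()] or
#'   [simulate_ground()]); must cover `[start - 24 h, start + n_days]`.
#' @param body_condition The bird's SMI (grams).
#' @param nest_id Nest identifier.
#' @param start POSIXct monitoring start.
#' @param n_days Monitored days.
#' @param re_occ,re_dur Nest-level random effects (logit / minutes).
#' @param seed Optional seed.
#' @return List with `trace` (nest trace tibble) and `truth` (tibble of
#'   planted bouts: onset, duration, class, pre-onset `temp_12h` /
#'   `temp_6h`, truncation flag).
#' @export
simulate_nest <- function(params, ground, body_condition, nest_id = "N1",
                          start = as.POSIXct("2019-06-20 00:00:00", tz = "UTC"),
                          n_days = 10, re_occ = 0, re_dur = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_days * 1440)
  ts <- start + 60 * (0:(n - 1L))
  tnum <- as.numeric(ts)
  if (min(ground$timestamp) > start - 86400 || max(ground$timestamp) < ts[n]) {
    abort("ground series must cover [start - 24 h, start + n_days]")
  }
  gi <- ground_index(ground)
  gidx <- as.integer(round((tnum - gi$origin) / 60)) + 1L
  gvec <- diff(c(0, gi$cum_temp))[gidx] # per-minute values (series is gap-free here)

  lt <- as.POSIXlt(ts, tz = "UTC")
  mod <- lt$hour * 60 + lt$min
  is_day <- mod >= 9 * 60 & mod < 17 * 60
  hvec <- params$recess_hazard *
    ifelse(is_day, 1, params$night_rate_factor)
  cumH <- cumsum(hvec)

  draw_short <- function() {
    repeat {
      d <- round(rlnorm(1, params$short_dur_logmean, params$short_dur_logsd))
      if (d >= params$min_duration) return(d)
    }
  }

  truth <- list()
  cur <- 0L # last consumed minute index (0 = none)
  repeat {
    base <- if (cur == 0L) 0 else cumH[cur]
    target <- base + rexp(1)
    j <- findInterval(target, cumH) + 1L
    if (j > n) break
    t12 <- window_mean_gi(gi, tnum[j], 12)
    t6 <- window_mean_gi(gi, tnum[j], 6)
    eta <- params$occ_beta0 + params$occ_betaT * (t12 - params$ground_mean) + re_occ
    extended <- rbinom(1, 1, plogis(eta)) == 1
    if (extended) {
      shift <- params$dur_beta0 +
        params$dur_betaT * (t6 - params$ground_mean) +
        params$dur_betaBC * (body_condition - params$bc_mean) +
        params$dur_betaTxBC * (t6 - params$ground_mean) *
          (body_condition - params$bc_mean) + re_dur
      D <- max(round(rlnorm(1, params$ext_dur_logmean, params$ext_dur_logsd) + shift),
               params$ext_min_duration)
    } else {
      D <- draw_short()
    }
    D_in <- min(D, n - j + 1L)
    truth[[length(truth) + 1L]] <- tibble::tibble(
      nest_id = nest_id, onset = ts[j], duration = D_in,
      class = if (extended) "extended" else "short",
      temp_12h = t12, temp_6h = t6,
      body_condition = body_condition, truncated = D_in < D
    )
    cur <- j + D_in # first incubation minute after the bout
    if (cur >= n) break
  }
  truth <- if (length(truth)) purrr::list_rbind(truth) else
    tibble::tibble(nest_id = character(), onset = as.POSIXct(character(), tz = "UTC"),
                   duration = numeric(), class = character(), temp_12h = numeric(),
                   temp_6h = numeric(), body_condition = numeric(), truncated = logical())

  temp <- rnorm(n, params$t_incubation, params$noise_sd)
  if (nrow(truth) > 0) {
    for (i in seq_len(nrow(truth))) {
      j <- as.integer(round((as.numeric(truth$onset[i]) - tnum[1]) / 60)) + 1L
      D <- truth$duration[i]
      k <- seq_len(D)
      idx <- j + k - 1L
      temp[idx] <- gvec[idx] +
        (params$t_incubation - gvec[idx]) * exp(-k / params$cooling_tau) +
        rnorm(D, 0, params$noise_sd)
    }
  }
  trace <- tibble::tibble(logger_id = paste0("L_", nest_id), nest_id = nest_id,
                          site = params$site, timestamp = ts, temp = temp)
  list(trace = trace, truth = truth)
}

#' Detectability margin of planted recesses
#'
#' Analytic check that, under the given parameters, the first minute of any
#' planted bout already drops more than `delta` below the largest plausible
#' daily maximum, so every planted bout of at least `min_duration` minutes
#' is recoverable by the max-drop rule. Returns the worst-case margin in
#' degrees C (positive = detectable).
#'
#' @param params A [sim_params()] list.
#' @param delta Detection drop, degrees C.
#' @export
detectability_margin <- function(params, delta = 4.5) {
  g_max <- params$ground_mean + params$ground_amp + 3 * params$ground_sd +
    3 * params$noise_sd
  drop1 <- (params$t_incubation - g_max) * (1 - exp(-1 / params$cooling_tau))
  noise_margin <- 6 * params$noise_sd # daily-max noise + recess-minute noise
  drop1 - delta - noise_margin
}

#' Simulate a full synthetic study bundle
#'
#' Generates everything the pipeline ingests, with known behavioural ground
#' truth: ground-reference loggers (shared weather, independent logger
#' noise) and the site ground series; one monitored nest trace per nest
#' with planted recesses; nest metadata; morphometrics consistent with each
#' bird's body condition via the scaled-mass allometry; and the truth
#' sidecar. Nest monitoring starts are staggered across the season so
#' nests sample different weather. Fully reproducible from `(params, seed)`.
#'
#' @param params A [sim_params()] list.
#' @param seed Integer seed.
#' @param start POSIXct monitoring start (midnight).
#' @return A list of class `recess_study`: `nest_traces`, `ground_loggers`,
#'   `ground`, `metadata`, `morphometrics`, `truth`, `params`, `seed`.
#' @export
simulate_study <- function(params = sim_params(), seed = 1,
                           start = as.POSIXct("2019-06-20 00:00:00", tz = "UTC")) {
  set.seed(seed)
  ground_start <- start - 86400
  ground_days <- params$days_per_nest + params$start_spread_days + 2
  n_gmin <- as.integer(ground_days * 1440)
  weather <- ar1_path(n_gmin, params$ground_ar1, params$ground_sd)
  ground_loggers <- purrr::map(seq_len(params$n_ground_loggers), function(i) {
    simulate_ground(params, ground_days, ground_start,
                    logger_id = paste0("G", i), weather = weather)
  }) |> purrr::list_rbind()
  ground <- build_ground_series(ground_loggers, site = params$site)

  nest_ids <- sprintf("N%03d", seq_len(params$n_nests))
  bc <- rnorm(params$n_nests, params$bc_mean, params$bc_sd)
  tarsus <- rnorm(params$n_nests, params$tarsus_mean, params$tarsus_sd)
  mass <- bc * (tarsus / params$tarsus_mean)^params$smi_exponent *
    exp(rnorm(params$n_nests, 0, 0.005))
  sex <- sample(c("M", "F"), params$n_nests, replace = TRUE)
  re_occ <- rnorm(params$n_nests, 0, params$occ_re_sd)
  re_dur <- rnorm(params$n_nests, 0, params$dur_re_sd)
  offset_days <- sample(0:params$start_spread_days, params$n_nests, replace = TRUE)
  starts <- start + offset_days * 86400

  sims <- purrr::map(seq_len(params$n_nests), function(i) {
    simulate_nest(params, ground, bc[i], nest_ids[i], starts[i],
                  params$days_per_nest, re_occ[i], re_dur[i])
  })
  nest_traces <- purrr::list_rbind(purrr::map(sims, "trace"))
  truth <- purrr::list_rbind(purrr::map(sims, "truth"))

  metadata <- tibble::tibble(
    nest_id = nest_ids, site = params$site, year = params$year,
    incubation_start = as.Date(starts, tz = "UTC") - 3,
    strategy = "uniparental", sex = sex,
    monitoring_start = starts,
    monitoring_end = starts + params$days_per_nest * 86400
  )
  morphometrics <- tibble::tibble(
    bird_id = paste0("B_", nest_ids), nest_id = nest_ids,
    mass = mass, tarsus = tarsus, sex = sex, capture_datetime = starts
  )
  structure(list(
    nest_traces = nest_traces, ground_loggers = ground_loggers,
    ground = ground, metadata = metadata, morphometrics = morphometrics,
    truth = truth, params = params, seed = seed
  ), class = "recess_study")
}

#' @export
print.recess_study <- function(x, ...) {
  cat(sprintf("Synthetic incubation study: %d nests x %d days, %d planted bouts (%.1f%% extended)\n",
              x$params$n_nests, x$params$days_per_nest, nrow(x$truth),
              100 * mean(x$truth$class == "extended")))
  invisible(x)
}

#' Write / read a study bundle as plain-text files
#'
#' Serializes a [simulate_study()] bundle to a directory of CSV files plus
#' a JSON sidecar (params, seed), the same interface a field study would
#' provide; `read_study_bundle()` restores it. Timestamps are written in
#' the canonical dialect, so a write/read round trip is exact to the
#' second.
#'
#' @param study A `recess_study`.
#' @param dir Output directory (created if needed).
#' @export
write_study_bundle <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(df) {
    for (cl in names(df)) {
      if (inherits(df[[cl]], "POSIXct")) {
        df[[cl]] <- format(df[[cl]], "%Y-%m-%d %H:%M:%S", tz = "UTC")
      }
    }
    df
  }
  readr::write_csv(fmt(study$nest_traces), file.path(dir, "nest_traces.csv"))
  readr::write_csv(fmt(study$ground_loggers), file.path(dir, "ground_loggers.csv"))
  readr::write_csv(fmt(study$metadata), file.path(dir, "metadata.csv"))
  readr::write_csv(fmt(study$morphometrics), file.path(dir, "morphometrics.csv"))
  readr::write_csv(fmt(study$truth), file.path(dir, "truth.csv"))
  jsonlite::write_json(list(seed = study$seed, params = unclass(study$params)),
                       file.path(dir, "bundle.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_study_bundle
#' @param dir Directory written by `write_study_bundle()`.
#' @export
read_study_bundle <- function(dir) {
  rd <- function(f, tcols = "timestamp") {
    df <- readr::read_csv(file.path(dir, f), show_col_types = FALSE, progress = FALSE)
    for (cl in intersect(tcols, names(df))) {
      df[[cl]] <- as.POSIXct(df[[cl]], tz = "UTC")
    }
    df
  }
  side <- jsonlite::read_json(file.path(dir, "bundle.json"), simplifyVector = TRUE)
  params <- structure(side$params, class = "sim_params")
  gl <- rd("ground_loggers.csv")
  structure(list(
    nest_traces = rd("nest_traces.csv"),
    ground_loggers = gl,
    ground = build_ground_series(gl, site = params$site),
    metadata = rd("metadata.csv", c("monitoring_start", "monitoring_end")),
    morphometrics = rd("morphometrics.csv", "capture_datetime"),
    truth = rd("truth.csv", "onset"),
    params = params, seed = side$seed
  ), class = "recess_study")
}
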