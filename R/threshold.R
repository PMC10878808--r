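#' Antimode of the recess-duration distribution
#'
#' Recess durations of uniparental incubators are strongly bimodal: a large
#' mode of short foraging bouts (minutes) and a small mode of extended,
#' self-maintenance recesses (hundreds of minutes). The local minimum of the
#' density between the two modes -- the *antimode* -- gives an objective
#' threshold separating the two classes. The density is estimated by a
#' Gaussian kernel on log-duration (default), where both modes are
#' approximately symmetric, and the antimode is back-transformed to minutes.
#'
#' The estimate is two-stage. Bimodality is first *validated* at the
#' critical bandwidth: starting from the base bandwidth (Sheather-Jones by
#' default), the smoothing is escalated to the smallest multiple with at
#' most two local maxima (for a Gaussian kernel the mode count is
#' non-increasing in bandwidth, so this is well defined); a density that
#' is already unimodal at the base bandwidth raises `"no antimode"`. The
#' two mode locations are read off that two-mode density. The antimode is
#' then *refined* as the minimum, between those modes, of the density at
#' half the critical bandwidth (floored at the base bandwidth) -- the
#' heavier critical-bandwidth smoothing is right for counting modes but
#' biases the location of the minimum. A numeric
#' `adjust` pins the bandwidth instead (single-stage); more than two modes
#' at that bandwidth is then an error naming the modes found.
#'
#' @param durations Recess durations in minutes (>= 50 values).
#' @param scale `"log"` (default) or `"natural"`: scale on which the kernel
#'   density is estimated.
#' @param bw Bandwidth rule or numeric value for [stats::density()];
#'   default Sheather-Jones (`"SJ"`), falling back to Silverman's rule if
#'   it fails on heavily discretized samples.
#' @param adjust `"auto"` (critical-bandwidth validation + base-bandwidth
#'   refinement) or a fixed bandwidth multiplier.
#' @param n_grid Density grid size.
#' @param stratum Optional label (e.g. `"2019/HOCH"`) carried in the result.
#' @return A `recess_threshold` object: list with `antimode`, `modes`
#'   (minutes, ascending), `ci_low`/`ci_high` (`NA` until bootstrapped),
#'   `n_boot`, `n`, `scale`, `bw` (base bandwidth used), `adjust`
#'   (escalation factor reached), `stratum`.
#' @export
estimate_antimode <- function(durations, scale = c("log", "natural"),
                              bw = "SJ", adjust = "auto", n_grid = 1024,
                              stratum = "pooled") {
  scale <- match.arg(scale)
  durations <- durations[is.finite(durations) & durations > 0]
  if (length(durations) < 50) {
    abort(sprintf("need >= 50 durations to estimate an antimode (got %d)",
                  length(durations)))
  }
  x <- if (scale == "log") log(durations) else durations
  if (sd(x) == 0) abort("no antimode: all durations identical")
  back <- function(v) if (scale == "log") exp(v) else v

  base <- if (is.numeric(bw)) bw else {
    tryCatch(density(x, bw = bw, n = 2)$bw,
             error = function(e) density(x, bw = "nrd0", n = 2)$bw)
  }
  turning_points <- function(a) {
    den <- density(x, bw = base * a, n = n_grid)
    turns <- diff(diff(den$y) > 0) # -1 at a max, +1 at a min
    list(den = den, max_i = which(turns == -1) + 1L,
         min_i = which(turns == 1) + 1L)
  }

  auto <- identical(adjust, "auto")
  a <- if (auto) 1 else adjust
  tp <- turning_points(a)
  if (auto && length(tp$max_i) > 2) {
    lo <- a
    while (length(tp$max_i) > 2 && a < 64) {
      lo <- a
      a <- a * 1.25
      tp <- turning_points(a)
    }
    if (length(tp$max_i) < 2) { # overshot: bisect back to two modes
      hi <- a
      for (i in 1:25) {
        mid <- (lo + hi) / 2
        tpm <- turning_points(mid)
        if (length(tpm$max_i) >= 2) lo <- mid else hi <- mid
        if (length(tpm$max_i) == 2) { a <- mid; tp <- tpm; break }
      }
    }
  }
  if (length(tp$max_i) < 2) {
    abort("no antimode: density is unimodal at this bandwidth")
  }
  if (length(tp$max_i) > 2) {
    abort(paste0("more than 2 modes at this bandwidth (at ",
                 paste(signif(back(tp$den$x[tp$max_i]), 4), collapse = ", "),
                 " min); increase `adjust` to smooth"))
  }
  m_lo <- tp$den$x[tp$max_i[1]]
  m_hi <- tp$den$x[tp$max_i[2]]
  if (auto && a > 1) {
    # refine the minimum with lighter smoothing than the mode count used,
    # floored at the base bandwidth so the valley stays smooth
    ref_den <- density(x, bw = max(base, base * a / 2), n = n_grid)
    sel <- which(ref_den$x > m_lo & ref_den$x < m_hi)
    anti <- ref_den$x[sel][which.min(ref_den$y[sel])]
  } else {
    between <- tp$min_i[tp$min_i > tp$max_i[1] & tp$min_i < tp$max_i[2]]
    anti <- tp$den$x[between[which.min(tp$den$y[between])]]
  }
  structure(list(
    antimode = back(anti),
    modes = back(c(m_lo, m_hi)),
    ci_low = NA_real_, ci_high = NA_real_,
    n_boot = 0L, n = length(durations),
    scale = scale, bw = base, adjust = a, stratum = stratum
  ), class = "recess_threshold")
}

#' @export
print.recess_threshold <- function(x, ...) {
  cat(sprintf(
    "Recess duration threshold (%s): antimode %.1f min (modes %.1f / %.1f)\n",
    x$stratum, x$antimode, x$modes[1], x$modes[2]))
  if (x$n_boot > 0) {
    cat(sprintf("  95%% bootstrap CI [%.1f, %.1f] (%d resamples, %d failed)\n",
                x$ci_low, x$ci_high, x$n_boot, x$n_failed))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.recess_threshold <- function(x, ...) {
  tibble::tibble(
    stratum = x$stratum, antimode = x$antimode,
    mode_short = x$modes[1], mode_extended = x$modes[2],
    ci_low = x$ci_low, ci_high = x$ci_high,
    n = x$n, n_boot = x$n_boot
  )
}

#' Bootstrap confidence interval for the antimode
#'
#' Nonparametric bootstrap of [estimate_antimode()]: durations are resampled
#' with replacement `n_boot` times (default 1000) and the percentile 95% CI
#' of the antimode is taken over the resamples in which a valid two-mode
#' estimate existed. Failed resamples are counted; more than 50% failures
#' aborts, since the distribution is then not reliably bimodal.
#'
#' @inheritParams estimate_antimode
#' @param n_boot Number of bootstrap resamples.
#' @param conf Confidence level of the percentile interval.
#' @param seed Optional integer seed for reproducibility.
#' @return A `recess_threshold` object with `ci_low`, `ci_high`, `n_boot`,
#'   `n_failed`, and the vector of resample antimodes in `boot_antimodes`.
#' @export
bootstrap_threshold <- function(durations, n_boot = 1000, conf = 0.95,
                                seed = NULL, scale = c("log", "natural"),
                                bw = "SJ", adjust = "auto", n_grid = 1024,
                                stratum = "pooled") {
  scale <- match.arg(scale)
  if (!is.null(seed)) set.seed(seed)
  est <- estimate_antimode(durations, scale = scale, bw = bw, adjust = adjust,
                           n_grid = n_grid, stratum = stratum)
  boots <- vapply(seq_len(n_boot), function(i) {
    d <- sample(durations, replace = TRUE)
    tryCatch(
      # base bandwidth frozen at the full-sample value across resamples
      estimate_antimode(d, scale = scale, bw = est$bw, adjust = adjust,
                        n_grid = n_grid, stratum = stratum)$antimode,
      error = function(e) NA_real_
    )
  }, numeric(1))
  n_failed <- sum(is.na(boots))
  if (n_failed > n_boot / 2) {
    abort(sprintf("bootstrap unstable: %d of %d resamples had no antimode",
                  n_failed, n_boot))
  }
  alpha <- (1 - conf) / 2
  ci <- quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  est$ci_low <- ci[1]
  est$ci_high <- ci[2]
  est$n_boot <- n_boot
  est$n_failed <- n_failed
  est$boot_antimodes <- boots
  est
}

#' Per-stratum bootstrap thresholds
#'
#' Runs [bootstrap_threshold()] within each (year, site) stratum of a
#' classified recess table, plus the pooled sample. Strata with fewer than
#' `min_n` recesses fall back to the pooled estimate (flagged in the
#' output).
#'
#' @param recesses Recess tibble with a `duration` column and the columns
#'   named in `strata`.
#' @param strata Character vector of stratifying columns.
#' @param min_n Minimum recesses for a stratum-specific estimate.
#' @param ... Passed to [bootstrap_threshold()].
#' @return Tibble of tidied thresholds, pooled row first.
#' @export
threshold_by_stratum <- function(recesses, strata = c("year", "site"),
                                 min_n = 100, ...) {
  pooled <- bootstrap_threshold(recesses$duration, stratum = "pooled", ...)
  out <- list(tidy(pooled))
  have <- strata[strata %in% names(recesses)]
  if (length(have) > 0) {
    groups <- recesses |>
      dplyr::group_by(dplyr::across(dplyr::all_of(have))) |>
      dplyr::group_split()
    for (g in groups) {
      label <- paste(unlist(g[1, have]), collapse = "/")
      if (nrow(g) < min_n) {
        row <- tidy(pooled)
        row$stratum <- paste0(label, " (pooled fallback)")
      } else {
        row <- tidy(tryCatch(
          bootstrap_threshold(g$duration, stratum = label, ...),
          error = function(e) pooled))
        row$stratum <- label
      }
      out[[length(out) + 1L]] <- row
    }
  }
  purrr::list_rbind(out)
}

#' Label recesses as short or extended
#'
#' A recess is *extended* when its duration is greater than or equal to the
#' threshold (boundary inclusive, so a duration exactly at the antimode is
#' extended), otherwise *short*.
#'
#' @param recesses Recess tibble with `duration`.
#' @param threshold Threshold in minutes, or a `recess_threshold` object.
#' @return `recesses` with a `class` factor column (`short`, `extended`).
#' @export
classify_recesses <- function(recesses, threshold) {
  if (inherits(threshold, "recess_threshold")) threshold <- threshold$antimode
  stopifnot(is.numeric(threshold), threshold > 0)
  dplyr::mutate(recesses, class = factor(
    dplyr::if_else(duration >= threshold, "extended", "short"),
    levels = c("short", "extended")
  ))
}

#' Linear discriminant for incubation strategy
#'
#' Incubation strategy (uniparental vs biparental) is assigned from daily
#' recess statistics with a linear discriminant whose coefficients come
#' from an external calibration on nests of known strategy; they are not
#' re-derived here and must be supplied. The score for a nest-day is
#' `intercept + w_n_recesses * n_recesses + w_mean_duration * mean duration`
#' and a positive score is labelled `positive_class`.
#'
#' @param intercept,w_n_recesses,w_mean_duration Discriminant coefficients.
#' @param positive_class Label assigned to positive scores.
#' @export
strategy_discriminant <- function(intercept, w_n_recesses, w_mean_duration,
                                  positive_class = c("uniparental", "biparental")) {
  if (missing(intercept) || missing(w_n_recesses) || missing(w_mean_duration)) {
    abort(paste0("strategy discriminant coefficients must be supplied from an ",
                 "external calibration (intercept, w_n_recesses, w_mean_duration)"))
  }
  structure(list(intercept = intercept, w_n_recesses = w_n_recesses,
                 w_mean_duration = w_mean_duration,
                 positive_class = match.arg(positive_class)),
            class = "strategy_discriminant")
}

#' Assign incubation strategy per nest
#'
#' Scores each nest-day with a [strategy_discriminant()], labels the nest by
#' majority over its days, and looks for a single biparental-to-uniparental
#' changepoint in the daily labels: a nest whose early days classify
#' biparental and later days uniparental is a *swap* nest (desertion of one
#' breeder), labelled with its change date.
#'
#' @param nest_days Tibble with `nest_id`, `date`, `n_recesses` and either a
#'   `mean_duration` column or `tdr` (mean duration then `tdr/n_recesses`).
#' @param discriminant A [strategy_discriminant()].
#' @return Tibble `nest_id`, `strategy` (`uniparental`, `biparental`,
#'   `swap`), `change_date` (`NA` unless swap), `prop_uniparental_days`.
#' @export
assign_strategy <- function(nest_days, discriminant) {
  if (!inherits(discriminant, "strategy_discriminant")) {
    abort("`discriminant` must be a strategy_discriminant()")
  }
  other <- setdiff(c("uniparental", "biparental"), discriminant$positive_class)
  nd <- nest_days |>
    dplyr::mutate(
      mean_duration = if ("mean_duration" %in% names(nest_days)) mean_duration
        else ifelse(n_recesses > 0, tdr / n_recesses, 0),
      score = discriminant$intercept +
        discriminant$w_n_recesses * n_recesses +
        discriminant$w_mean_duration * mean_duration,
      label = ifelse(score > 0, discriminant$positive_class, other)
    )
  nd |>
    dplyr::group_by(nest_id) |>
    dplyr::arrange(date, .by_group = TRUE) |>
    dplyr::summarise(
      strategy = {
        lab <- label
        uni <- lab == "uniparental"
        majority <- if (mean(uni) >= 0.5) "uniparental" else "biparental"
        # single changepoint: biparental prefix then uniparental suffix
        n <- length(lab)
        best <- NA_integer_
        if (n >= 4) {
          mis_flat <- min(sum(uni), sum(!uni))
          for (k in 2:(n - 1)) {
            mis <- sum(uni[1:(k - 1)]) + sum(!uni[k:n])
            if (mis < mis_flat && mis <= 0.1 * n) {
              mis_flat <- mis
              best <- k
            }
          }
        }
        if (!is.na(best)) "swap" else majority
      },
      change_date = {
        lab <- label
        uni <- lab == "uniparental"
        n <- length(lab)
        cd <- as.Date(NA)
        if (n >= 4) {
          mis_flat <- min(sum(uni), sum(!uni))
          for (k in 2:(n - 1)) {
            mis <- sum(uni[1:(k - 1)]) + sum(!uni[k:n])
            if (mis < mis_flat && mis <= 0.1 * n) {
              mis_flat <- mis
              cd <- date[k]
            }
          }
        }
        cd
      },
      prop_uniparental_days = mean(label == "uniparental"),
      .groups = "drop"
    )
}
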