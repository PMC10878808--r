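# Independent oracles and fixture builders. These deliberately re-derive
# results by the most naive route available (per-minute loops, grid search)
# so they share no code with the implementation they check.

# Build a single-nest trace tibble from a plain temperature vector at 1-min
# resolution. `drop_minutes` (1-based indices) are removed to create gaps.
make_trace <- function(temps, start = as.POSIXct("2021-06-20 00:00:00", tz = "UTC"),
                       nest_id = "N1", logger_id = "L1", site = "S",
                       drop_minutes = integer(0)) {
  n <- length(temps)
  ts <- start + 60 * (0:(n - 1))
  keep <- setdiff(seq_len(n), drop_minutes)
  tibble::tibble(logger_id = logger_id, nest_id = nest_id, site = site,
                 timestamp = ts[keep], temp = temps[keep])
}

# Brute-force recess scan: walk the record minute by minute, holding the
# threshold of the run's onset day, terminating runs at gaps.
oracle_detect <- function(trace, delta = 4.5, min_dur = 3) {
  ts <- trace$timestamp
  temp <- trace$temp
  day <- as.Date(ts, tz = "UTC")
  thr <- tapply(temp, day, max) - delta
  n <- length(ts)
  out <- list()
  i <- 1
  while (i <= n) {
    if (temp[i] < thr[[as.character(day[i])]]) {
      onset_thr <- thr[[as.character(day[i])]]
      j <- i
      while (j < n && temp[j + 1] < onset_thr &&
             as.numeric(ts[j + 1]) - as.numeric(ts[j]) == 60) {
        j <- j + 1
      }
      if (j - i + 1 >= min_dur) {
        out[[length(out) + 1]] <- data.frame(onset = ts[i], duration = j - i + 1)
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (length(out) == 0) {
    return(data.frame(onset = as.POSIXct(character(), tz = "UTC"),
                      duration = numeric()))
  }
  do.call(rbind, out)
}

# Density minimum of a two-component lognormal mixture between its modes,
# found by grid search on a 0.01 step log grid.
oracle_mixture_antimode <- function(w1, mu1, s1, mu2, s2, step = 0.01) {
  grid <- seq(mu1, mu2, by = step)
  dens <- w1 * dnorm(grid, mu1, s1) + (1 - w1) * dnorm(grid, mu2, s2)
  exp(grid[which.min(dens)])
}

# Tiny deterministic study used by several pipeline-level tests; built once.
cached_mini_report <- local({
  report <- NULL
  function() {
    if (is.null(report)) {
      cfg <- run_config(seed = 42,
                        sim = sim_params(n_nests = 12, days_per_nest = 6),
                        n_boot = 100)
      report <<- suppressWarnings(run_pipeline(cfg))
    }
    report
  }
})
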