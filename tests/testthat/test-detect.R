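flat_day_with_dip <- function(dip_at, dip_len, dip_temp, base = 38, days = 1) {
  x <- rep(base, 1440 * days)
  x[dip_at:(dip_at + dip_len - 1)] <- dip_temp
  x
}

test_that("a clear dip is detected with exact onset and duration", {
  tr <- make_trace(flat_day_with_dip(601, 10, 30))
  r <- detect_recesses(tr, detection_params())
  expect_equal(nrow(r), 1)
  expect_equal(r$duration, 10)
  expect_equal(r$onset, tr$timestamp[601])
  expect_equal(r$end, tr$timestamp[601] + 10 * 60)
})

test_that("the 4.5 degree drop rule and 3-minute minimum are enforced", {
  # drop of 4.0 degrees below the daily max: not a recess
  r1 <- detect_recesses(make_trace(flat_day_with_dip(601, 10, 34)))
  expect_equal(nrow(r1), 0)
  # 2-minute dip, however deep: below the minimum duration
  r2 <- detect_recesses(make_trace(flat_day_with_dip(601, 2, 30)))
  expect_equal(nrow(r2), 0)
  # a minute exactly at threshold (max - 4.5) counts as incubation
  r3 <- detect_recesses(make_trace(flat_day_with_dip(601, 10, 33.5)))
  expect_equal(nrow(r3), 0)
  # just below threshold is a recess
  r4 <- detect_recesses(make_trace(flat_day_with_dip(601, 10, 33.49)))
  expect_equal(nrow(r4), 1)
})

test_that("runs crossing midnight stay one recess under the onset-day threshold", {
  # 100-minute dip starting 23:30 of day 1
  x <- flat_day_with_dip(1411, 100, 30, days = 2)
  r <- detect_recesses(make_trace(x))
  expect_equal(nrow(r), 1)
  expect_equal(r$duration, 100)
  expect_equal(r$day_of_onset, as.Date("2021-06-20"))
  tdr <- compute_tdr(r)
  expect_equal(tdr$tdr, c(30, 70))
  expect_equal(tdr$n_recesses, c(1L, 0L))
})

test_that("gaps terminate recess runs and no temperatures are invented", {
  x <- flat_day_with_dip(601, 30, 30)
  tr <- make_trace(x, drop_minutes = 611:615)
  r <- detect_recesses(tr)
  expect_equal(nrow(r), 2)
  expect_equal(sort(r$duration), c(10, 15))
})

test_that("TDR sums recess minutes and splits at midnight", {
  x <- rep(38, 1440)
  x[101:110] <- 30; x[301:320] <- 30; x[501:530] <- 30
  tdr <- compute_tdr(detect_recesses(make_trace(x)))
  expect_equal(tdr$tdr, 60)
  expect_equal(tdr$n_recesses, 3L)
  expect_equal(nrow(compute_tdr(detect_recesses(make_trace(rep(38, 1440))))), 0)
})

test_that("per-nest TDR conserves total detected recess minutes", {
  st <- simulate_study(sim_params(n_nests = 4, days_per_nest = 3), seed = 3)
  r <- detect_recesses(st$nest_traces)
  tdr <- compute_tdr(r)
  by_nest_tdr <- tapply(tdr$tdr, tdr$nest_id, sum)
  by_nest_dur <- tapply(r$duration, r$nest_id, sum)
  expect_equal(as.numeric(by_nest_tdr[names(by_nest_dur)]),
               as.numeric(by_nest_dur))
})

test_that("raising the required drop never increases detections", {
  set.seed(7)
  for (i in 1:10) {
    x <- 38 + rnorm(1440, 0, 0.3)
    dips <- sample(50:1350, 5)
    for (d in dips) x[d:(d + sample(3:40, 1))] <- runif(1, 25, 36)
    tr <- make_trace(x)
    counts <- vapply(c(2, 3, 4.5, 6, 9), function(delta) {
      nrow(detect_recesses(tr, detection_params(delta_max_drop = delta)))
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("detection equals the brute-force maximal-run oracle on random days", {
  st <- simulate_study(sim_params(n_nests = 3, days_per_nest = 4), seed = 11)
  for (nid in unique(st$nest_traces$nest_id)) {
    tr <- dplyr::filter(st$nest_traces, nest_id == nid)
    got <- detect_recesses(tr)
    want <- oracle_detect(tr)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$onset, want$onset)
    expect_equal(got$duration, want$duration)
  }
})

test_that("short monitoring yields no recesses and flags the nest", {
  tr <- make_trace(flat_day_with_dip(301, 10, 30)[1:1380]) # 23 h
  r <- detect_recesses(tr)
  expect_equal(nrow(r), 0)
  expect_identical(attr(r, "flagged_short"), "N1")
})

test_that("quality filters annotate days with reason codes", {
  good <- flat_day_with_dip(601, 10, 30)
  cold <- rep(36, 1440) # daily max below the 37.5 floor
  tr <- dplyr::bind_rows(
    make_trace(c(good, cold), nest_id = "A", logger_id = "LA"),
    make_trace(good[1:1380], nest_id = "B", logger_id = "LB") # 23 h
  )
  r <- detect_recesses(tr)
  nd <- apply_quality_filters(
    nest_day_summary(tr, r), detection_params(),
    manual_exclusions = tibble::tibble(nest_id = "A", date = as.Date("2021-06-20"))
  )
  reasons <- setNames(nd$excluded_reason, paste(nd$nest_id, nd$date))
  expect_equal(reasons[["A 2021-06-21"]], "daily_max_below_floor")
  expect_equal(reasons[["A 2021-06-20"]], "manual_erratic")
  expect_equal(reasons[["B 2021-06-20"]], "short_monitoring")
  expect_true(all(!nd$quality_pass))
})

test_that("capture-flagged recesses are excluded with an accounted reason", {
  x <- rep(38, 1440)
  x[101:110] <- 30; x[501:530] <- 30
  tr <- make_trace(x)
  r <- detect_recesses(tr)
  caps <- tibble::tibble(nest_id = "N1", datetime = tr$timestamp[105])
  r <- flag_captures(r, caps)
  expect_equal(sum(r$is_capture_artifact), 1)
  nd <- apply_quality_filters(nest_day_summary(tr, r))
  kept <- filter_recesses(r, nd)
  expect_equal(nrow(kept), 1)
  report <- attr(kept, "exclusions")
  expect_equal(report$n_excluded[report$excluded_reason == "capture_artifact"], 1L)
  # ledger conservation: in = out + excluded
  expect_equal(nrow(r), nrow(kept) + sum(report$n_excluded))
})

test_that("max-drop and median-drop concur on short recesses on clean traces", {
  x <- rep(38, 1440 * 2)
  for (d in c(101, 301, 601, 901, 1501, 1801, 2101)) x[d:(d + 9)] <- 28
  cmp <- compare_methods(make_trace(x))
  expect_equal(nrow(cmp$matches), 7)
  expect_true(all(cmp$matches$matched))
  expect_true(all(cmp$matches$overlap_fraction == 1))
  expect_equal(nrow(cmp$unmatched_median), 0)
  # empty trace day yields an empty comparison
  cmp0 <- compare_methods(make_trace(rep(38, 1440)))
  expect_equal(nrow(cmp0$matches), 0)
})
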