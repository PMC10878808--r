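test_that("scaled mass index reduces to mass at the reference length", {
  set.seed(3)
  tarsus <- rnorm(30, 25, 1)
  mass <- 55 * (tarsus / 25)^2.2 * exp(rnorm(30, 0, 0.02))
  m <- tibble::tibble(mass = mass, tarsus = tarsus)
  out <- scaled_mass_index(m, ref_length = 25)
  # a bird whose tarsus equals L0 keeps its mass
  probe <- scaled_mass_index(
    dplyr::bind_rows(m, tibble::tibble(mass = 50, tarsus = 25)),
    ref_length = 25)
  expect_equal(probe$smi[31], 50, tolerance = 1e-6)
  expect_true(all(out$smi > 0))
})

test_that("SMA exponent is exact on a perfectly isometric sample", {
  tarsus <- seq(22, 28, length.out = 20)
  mass <- exp(3 * log(tarsus) + log(55) - 3 * log(25))
  out <- scaled_mass_index(tibble::tibble(mass = mass, tarsus = tarsus))
  expect_equal(attr(out, "b_sma"), 3, tolerance = 1e-10)
  expect_equal(attr(out, "r"), 1, tolerance = 1e-10)
  # r = 1 means b_SMA equals the OLS slope; all SMI collapse to mass at L0
  expect_equal(out$smi, rep(out$smi[1], 20), tolerance = 1e-8)
})

test_that("SMI is invariant to bird order and to unit rescaling with L0", {
  set.seed(9)
  m <- tibble::tibble(mass = runif(25, 45, 65), tarsus = rnorm(25, 25, 1))
  a <- scaled_mass_index(m, ref_length = 25)
  b <- scaled_mass_index(m[sample(25), ], ref_length = 25)
  expect_equal(sort(a$smi), sort(b$smi))
  scaled <- dplyr::mutate(m, tarsus = tarsus * 10)
  c_ <- scaled_mass_index(scaled, ref_length = 250)
  expect_equal(c_$smi, a$smi, tolerance = 1e-10)
  expect_error(scaled_mass_index(m[1:2, ]), ">= 3")
  expect_error(scaled_mass_index(tibble::tibble(mass = c(50, 50, 50),
                                                tarsus = c(24, 25, 26))),
               "undefined")
})

test_that("window means use the half-open pre-onset window with coverage floor", {
  start <- as.POSIXct("2021-06-20 00:00:00", tz = "UTC")
  gs <- make_trace(rep(10, 1440), start = start, nest_id = NA, logger_id = "ground")
  t0 <- start + 12 * 3600
  for (h in c(1, 2, 6, 12)) {
    expect_equal(window_mean_ground_temp(gs, t0, h), 10)
  }
  # 5 then 15 degrees over a 12 h window
  gs2 <- make_trace(c(rep(5, 360), rep(15, 360), rep(10, 720)), start = start)
  expect_equal(window_mean_ground_temp(gs2, start + 12 * 3600, 12), 10)
  # onset minute itself is excluded: only the minute before t0 matters
  gs3 <- make_trace(c(rep(0, 59), 30, rep(99, 100)), start = start)
  expect_equal(window_mean_ground_temp(gs3, start + 60 * 60, 1),
               mean(c(rep(0, 59), 30)))
  # coverage below 50% gives NA; above the floor, the covered mean
  gs4 <- make_trace(rep(10, 1440), start = start, drop_minutes = 1:400)
  expect_true(is.na(window_mean_ground_temp(gs4, start + 720 * 60, 12)))
  gs5 <- make_trace(rep(10, 1440), start = start, drop_minutes = 1:180)
  expect_equal(window_mean_ground_temp(gs5, start + 720 * 60, 12), 10)
})

test_that("window means match a trapezoid oracle on a sinusoidal day", {
  start <- as.POSIXct("2021-06-20 00:00:00", tz = "UTC")
  x <- 10 + 6 * sin(2 * pi * (0:2879) / 1440)
  gs <- make_trace(x, start = start)
  t0 <- start + 30 * 3600
  for (h in c(1, 6, 24)) {
    oracle <- mean(x[(30 * 60 - h * 60 + 1):(30 * 60)])
    expect_equal(window_mean_ground_temp(gs, t0, h), oracle, tolerance = 1e-10)
  }
})

test_that("a 24 h window is the mean of its 1 h tiles on gapless data", {
  set.seed(21)
  start <- as.POSIXct("2021-06-20 00:00:00", tz = "UTC")
  gs <- make_trace(rnorm(2880, 10, 3), start = start)
  t0 <- start + 36 * 3600
  tiles <- vapply(0:23, function(k) {
    window_mean_ground_temp(gs, t0 - k * 3600, 1)
  }, numeric(1))
  expect_equal(window_mean_ground_temp(gs, t0, 24), mean(tiles), tolerance = 1e-10)
})

test_that("day/night assignment partitions the clock as 480 + 960 minutes", {
  base <- as.POSIXct("2021-06-20 00:00:00", tz = "UTC")
  expect_equal(as.character(assign_period(base + 17 * 3600)), "night")
  expect_equal(as.character(assign_period(base + 9 * 3600)), "day")
  expect_equal(as.character(assign_period(base + 12 * 3600)), "day")
  expect_equal(as.character(assign_period(base + 3 * 3600)), "night")
  all_minutes <- assign_period(base + 60 * (0:1439))
  expect_equal(sum(all_minutes == "day"), 480)
  expect_equal(sum(all_minutes == "night"), 960)
})

test_that("the covariate builder assembles windows, condition and timing", {
  st <- simulate_study(sim_params(n_nests = 3, days_per_nest = 3), seed = 2)
  r <- classify_recesses(detect_recesses(st$nest_traces), 120)
  smi <- scaled_mass_index(st$morphometrics)
  cov <- build_recess_covariates(r, st$ground, st$metadata,
                                 condition = dplyr::rename(smi, smi = smi))
  expect_true(all(c("temp_1h", "temp_12h", "temp_24h", "body_condition",
                    "incubation_date", "period", "nest_type", "extended")
                  %in% names(cov)))
  expect_true(all(cov$incubation_date >= 0))
  expect_equal(nrow(cov), nrow(r))
  # window covariates agree with the generator's own pre-onset means
  truth_t12 <- st$truth$temp_12h[match(cov$onset, st$truth$onset)]
  ok <- !is.na(cov$temp_12h) & !is.na(truth_t12)
  expect_gt(sum(ok), 0)
  expect_equal(cov$temp_12h[ok], truth_t12[ok], tolerance = 1e-8)
})
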