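mixture_durations <- function(n, w_ext = 0.02, mu1 = log(7), s1 = 0.9,
                              mu2 = log(340), s2 = 0.3) {
  n_ext <- round(n * w_ext)
  draw <- function(m, mu, s) { # integer minutes, >= 3 by rejection
    out <- numeric(0)
    while (length(out) < m) {
      d <- round(rlnorm(2 * m, mu, s))
      out <- c(out, d[d >= 3])
    }
    out[seq_len(m)]
  }
  c(draw(n - n_ext, mu1, s1), draw(n_ext, mu2, s2))
}

test_that("antimode lands between the two modes of a bimodal mixture", {
  set.seed(101)
  d <- mixture_durations(4000)
  th <- estimate_antimode(d)
  expect_length(th$modes, 2)
  expect_lt(th$modes[1], th$antimode)
  expect_gt(th$modes[2], th$antimode)
  expect_lt(abs(log(th$modes[1]) - log(7)), 0.5)
  expect_lt(abs(log(th$modes[2]) - log(340)), 0.5)
})

test_that("degenerate and unimodal samples are refused", {
  expect_error(estimate_antimode(rep(10, 100)), "identical")
  set.seed(5)
  expect_error(estimate_antimode(rlnorm(500, log(10), 0.5)), "unimodal")
  expect_error(estimate_antimode(1:10), ">= 50")
})

test_that("antimode scales with the durations on the log scale", {
  set.seed(7)
  d <- mixture_durations(3000)
  th1 <- estimate_antimode(d)
  th2 <- estimate_antimode(d * 10)
  expect_equal(th2$antimode / th1$antimode, 10, tolerance = 0.02)
  # label partition is preserved relative to the scaled threshold
  c1 <- classify_recesses(tibble::tibble(duration = d), th1)
  c2 <- classify_recesses(tibble::tibble(duration = d * 10),
                          th1$antimode * th2$antimode / th1$antimode)
  expect_gt(mean(c1$class == c2$class), 0.995)
})

test_that("classification is an inclusive-boundary partition", {
  r <- tibble::tibble(duration = c(7, 119.3, 340, 118, 120))
  out <- classify_recesses(r, 119.3)
  expect_equal(as.character(out$class),
               c("short", "extended", "extended", "short", "extended"))
  expect_equal(sum(out$class == "short") + sum(out$class == "extended"), nrow(r))
})

test_that("bootstrap CI is reproducible, ordered, and degenerate at n_boot = 1", {
  set.seed(33)
  d <- mixture_durations(1500)
  b1 <- bootstrap_threshold(d, n_boot = 50, seed = 9)
  b2 <- bootstrap_threshold(d, n_boot = 50, seed = 9)
  expect_identical(b1$boot_antimodes, b2$boot_antimodes)
  expect_lte(b1$ci_low, b1$ci_high)

  b3 <- bootstrap_threshold(d, n_boot = 1, seed = 4)
  expect_equal(b3$ci_low, b3$ci_high)
  expect_equal(b3$ci_low, b3$boot_antimodes[1])
})

test_that("bootstrap CI width shrinks with sample size", {
  widths <- sapply(1:8, function(s) {
    set.seed(500 + s)
    small <- mixture_durations(500, w_ext = 0.1)
    big <- mixture_durations(5000, w_ext = 0.1)
    w <- function(d) {
      b <- bootstrap_threshold(d, n_boot = 100, seed = s)
      b$ci_high - b$ci_low
    }
    c(small = w(small), big = w(big))
  })
  expect_lt(median(widths["big", ]), median(widths["small", ]))
})

test_that("stratified thresholds return pooled plus per-stratum rows", {
  set.seed(12)
  r <- tibble::tibble(
    duration = mixture_durations(2000, w_ext = 0.05),
    year = rep(c(2018L, 2019L), each = 1000),
    site = "S"
  )
  tab <- threshold_by_stratum(r, n_boot = 30, seed = 2)
  expect_equal(tab$stratum[1], "pooled")
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$antimode > tab$mode_short & tab$antimode < tab$mode_extended))
})

test_that("strategy assignment needs coefficients and separates regimes", {
  expect_error(strategy_discriminant(), "supplied")
  # discriminant: uniparental when n_recesses > 15
  disc <- strategy_discriminant(-15, 1, 0, positive_class = "uniparental")
  uni_days <- tibble::tibble(nest_id = "U", date = as.Date("2021-06-20") + 0:5,
                             n_recesses = c(24, 22, 25, 23, 21, 26), tdr = 250)
  bi_days <- tibble::tibble(nest_id = "B", date = as.Date("2021-06-20") + 0:5,
                            n_recesses = c(9, 10, 8, 11, 9, 10), tdr = 90)
  out <- assign_strategy(dplyr::bind_rows(uni_days, bi_days), disc)
  expect_equal(out$strategy[out$nest_id == "U"], "uniparental")
  expect_equal(out$strategy[out$nest_id == "B"], "biparental")
  expect_true(all(is.na(out$change_date)))
})

test_that("a biparental-to-uniparental switch is detected as a swap nest", {
  disc <- strategy_discriminant(-15, 1, 0)
  days <- tibble::tibble(
    nest_id = "S1", date = as.Date("2021-06-20") + 0:9,
    n_recesses = c(9, 10, 8, 9, 24, 23, 25, 22, 24, 23), tdr = 150
  )
  out <- assign_strategy(days, disc)
  expect_equal(out$strategy, "swap")
  expect_equal(out$change_date, as.Date("2021-06-24"))
  # constant labels: no changepoint
  same <- tibble::tibble(nest_id = "C", date = as.Date("2021-06-20") + 0:9,
                         n_recesses = 20, tdr = 200)
  expect_equal(assign_strategy(same, disc)$strategy, "uniparental")
})
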