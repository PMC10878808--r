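# small mixed-model dataset with known structure
make_lmm_data <- function(n_nests = 15, per_nest = 30, beta = 2, re_sd = 1,
                          resid_sd = 1, seed = 1) {
  set.seed(seed)
  nest <- rep(sprintf("n%02d", 1:n_nests), each = per_nest)
  re <- rep(rnorm(n_nests, 0, re_sd), each = per_nest)
  x <- rnorm(n_nests * per_nest, 10, 3)
  tibble::tibble(nest_id = nest, x = x,
                 y = 5 + beta * x + re + rnorm(length(x), 0, resid_sd))
}

test_that("gaussian LMM recovers slopes in raw units after Z-scoring", {
  d <- make_lmm_data()
  f <- fit_mixed_model(d, "y", "x", family = "gaussian")
  td <- tidy(f, raw_units = TRUE)
  expect_equal(unname(td$estimate[td$term == "x"]), 2, tolerance = 0.05)
  expect_true(all(c("df", "p.value") %in% names(td)))
  g <- glance(f)
  expect_gt(g$r2_conditional, g$r2_marginal)
  expect_true(g$r2_conditional <= 1 && g$r2_marginal >= 0)
})

test_that("raw-unit slopes are invariant to affine predictor rescaling", {
  d <- make_lmm_data()
  f1 <- fit_mixed_model(d, "y", "x")
  d2 <- dplyr::mutate(d, x = 9 * x / 5 + 32) # change of units
  f2 <- fit_mixed_model(d2, "y", "x")
  s1 <- tidy(f1, raw_units = TRUE)$estimate[2]
  s2 <- tidy(f2, raw_units = TRUE)$estimate[2]
  expect_equal(s2 * 9 / 5, s1, tolerance = 1e-6)
  expect_equal(f1$aic, f2$aic, tolerance = 1e-6)
})

test_that("null gaussian models keep slope statistics small across seeds", {
  zs <- vapply(1:10, function(s) {
    d <- make_lmm_data(beta = 0, seed = 100 + s)
    f <- fit_mixed_model(d, "y", "x")
    abs(tidy(f)$statistic[2])
  }, numeric(1))
  expect_true(all(zs < 3))
})

test_that("zero between-nest variance collapses conditional onto marginal R2", {
  d <- make_lmm_data(re_sd = 0, seed = 3)
  f <- suppressWarnings(fit_mixed_model(d, "y", "x"))
  expect_lt(f$r2[["conditional"]] - f$r2[["marginal"]], 0.01)
})

test_that("Nakagawa R2 matches a direct variance computation for a logit GLMM", {
  set.seed(11)
  n_nests <- 40; per_nest <- 100
  nest <- rep(sprintf("n%02d", 1:n_nests), each = per_nest)
  re <- rep(rnorm(n_nests, 0, 0.8), each = per_nest)
  x <- rnorm(n_nests * per_nest)
  eta <- -1 + 0.9 * x + re
  d <- tibble::tibble(nest_id = nest, x = x, y = rbinom(length(x), 1, plogis(eta)))
  f <- fit_mixed_model(d, "y", "x", family = "binomial")
  # brute-force: variance of the fitted fixed-effect linear predictor
  fe <- lme4::fixef(f$model)
  xz <- (x - mean(x)) / sd(x)
  var_f <- var(fe[["(Intercept)"]] + fe[["x"]] * xz)
  var_r <- unname(lme4::VarCorr(f$model)$nest_id[1])
  want <- var_f / (var_f + var_r + pi^2 / 3)
  expect_equal(unname(f$r2[["marginal"]]), want, tolerance = 0.02)
  # a predictor with no effect explains (almost) nothing
  d0 <- dplyr::mutate(d, y = rbinom(dplyr::n(), 1, 0.3))
  f0 <- suppressWarnings(fit_mixed_model(d0, "y", "x", family = "binomial"))
  expect_lt(f0$r2[["marginal"]], 0.01)
})

test_that("identical covariate columns give identical AIC in window comparison", {
  d <- make_lmm_data()
  d$temp_1h <- d$x
  d$temp_2h <- d$x
  opt <- optimize_time_window(d, "y", fixed = character(0), windows = c(1, 2))
  expect_equal(opt$table$aic[1], opt$table$aic[2], tolerance = 1e-9)
  expect_true(all(opt$table$supported))
  expect_equal(opt$table$n_obs[1], opt$table$n_obs[2])
})

test_that("Johnson-Neyman bounds match the quadratic-formula oracle", {
  # fabricated coefficients: roots of (-2 + m)^2 = 4 (0.04 + 0.01 m^2)
  got <- jn_bounds(b_t = -2, b_tm = 1, var_t = 0.04, var_tm = 0.01,
                   cov_ttm = 0, t_crit = 2)
  A <- 1 - 4 * 0.01; B <- 2 * (-2); C <- 4 - 4 * 0.04
  oracle <- sort(c((-B - sqrt(B^2 - 4 * A * C)) / (2 * A),
                   (-B + sqrt(B^2 - 4 * A * C)) / (2 * A)))
  expect_equal(got$lower, oracle[1], tolerance = 1e-6)
  expect_equal(got$upper, oracle[2], tolerance = 1e-6)
  expect_equal(got$status, "two_roots")

  # no interaction: constant slope, no boundary
  none <- jn_bounds(2, 0, 0.1, 0, 0, 2)
  expect_equal(none$status, "all_significant")
  ns <- jn_bounds(0.1, 0, 0.1, 0, 0, 2)
  expect_equal(ns$status, "none_significant")
})

test_that("between real JN roots the slope is non-significant when A > 0", {
  b <- jn_bounds(b_t = -2, b_tm = 1, var_t = 0.04, var_tm = 0.01, cov_ttm = 0,
                 t_crit = 2)
  probe <- seq(b$lower + 1e-6, b$upper - 1e-6, length.out = 25)
  tstat <- abs((-2 + probe) / sqrt(0.04 + 0.01 * probe^2))
  expect_true(all(tstat < 2))
  outside <- c(b$lower - 0.5, b$upper + 0.5)
  expect_true(all(abs((-2 + outside) / sqrt(0.04 + 0.01 * outside^2)) > 2))
})

test_that("simple slopes on a fitted interaction agree with hand computation", {
  set.seed(23)
  n <- 600
  nest <- rep(sprintf("n%02d", 1:20), each = 30)
  tmp <- rnorm(n, 10, 3); mod <- rnorm(n, 55, 6)
  y <- 300 - 8 * (tmp - 10) + 0.9 * (tmp - 10) * (mod - 55) +
    rep(rnorm(20, 0, 20), each = 30) + rnorm(n, 0, 40)
  d <- tibble::tibble(nest_id = nest, temp = tmp, bc = mod, y = y)
  f <- fit_mixed_model(d, "y", c("temp", "bc"), interaction = c("temp", "bc"))
  jn <- simple_slopes_jn(f, "temp", "bc")
  # conditional slope at the median probe from the coefficients directly
  fe <- lme4::fixef(f$model)
  sc <- f$scaling
  mz <- (jn$slopes$moderator_value[2] - sc$center[sc$term == "bc"]) /
    sc$scale[sc$term == "bc"]
  want <- (fe[["temp"]] + fe[["temp:bc"]] * mz) / sc$scale[sc$term == "temp"]
  expect_equal(jn$slopes$slope[2], unname(want), tolerance = 1e-8)
  expect_equal(nrow(jn$jn), 2)
  # FDR-adjusted critical value is never below the nominal one
  expect_gte(jn$jn$t_crit[2], jn$jn$t_crit[1])
  expect_error(simple_slopes_jn(fit_mixed_model(d, "y", c("temp", "bc")),
                                "temp", "bc"), "interaction")
})

test_that("interaction selection prefers higher marginal R2 with tie to simpler", {
  d <- make_lmm_data()
  f <- fit_mixed_model(d, "y", "x")
  tie <- select_interaction_model(f, f)
  expect_equal(tie$selected, "without")
  set.seed(31)
  n <- 900
  nest <- rep(sprintf("n%02d", 1:30), each = 30)
  tmp <- rnorm(n, 10, 3); mod <- rnorm(n, 55, 6)
  y <- 300 - 8 * (tmp - 10) + 1.2 * (tmp - 10) * (mod - 55) + rnorm(n, 0, 60)
  d2 <- tibble::tibble(nest_id = nest, temp = tmp, bc = mod, y = y)
  fw <- suppressWarnings(
    fit_mixed_model(d2, "y", c("temp", "bc"), interaction = c("temp", "bc")))
  fo <- suppressWarnings(fit_mixed_model(d2, "y", c("temp", "bc")))
  expect_equal(select_interaction_model(fw, fo)$selected, "with")
})

test_that("model fitting validates its inputs", {
  d <- make_lmm_data()
  expect_error(fit_mixed_model(d, "y", "missing_col"), "lacks")
  expect_error(fit_mixed_model(d[d$nest_id == "n01", ], "y", "x"), "grouping")
})

test_that("occurrence summary converts the logit slope to a per-degree change", {
  set.seed(41)
  n <- 4000
  nest <- rep(sprintf("n%02d", 1:40), each = 100)
  tmp <- rnorm(n, 10, 3)
  y <- rbinom(n, 1, plogis(-3.9 - 0.22 * (tmp - 10)))
  d <- tibble::tibble(nest_id = nest, temp = tmp, y = y)
  f <- suppressWarnings(fit_mixed_model(d, "y", "temp", family = "binomial"))
  odds <- prob_change_per_degree(f, "temp", scale = "odds")
  expect_equal(odds, exp(-0.22) - 1, tolerance = 0.35)
  pr <- prob_change_per_degree(f, "temp", scale = "probability")
  expect_lt(pr, 0) # rarer with warming
  expect_gt(pr, -0.5)
})
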