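#' Fit an occurrence, duration, or TDR mixed model
#'
#' Single fitting surface for the three model families used in the
#' analysis: the extended-recess occurrence model (binomial GLMM, logit
#' link, Laplace approximation), and the duration and TDR models (Gaussian
#' LMMs). Numeric predictors are Z-scored before fitting (centers and
#' scales are retained, so estimates can be back-transformed to raw units);
#' the response is left on its original scale. A random intercept for nest
#' identity is always included. Gaussian models default to maximum
#' likelihood so that AICs are comparable across fixed-effect structures;
#' set `reml = TRUE` for REML variance estimates on a final model.
#'
#' A singular random-effect fit (variance estimated at zero) is kept with a
#' warning; an optimizer convergence failure is an error carrying the
#' optimizer messages.
#'
#' @param data Covariate/response tibble (one row per recess or nest-day).
#' @param response Response column name (`extended` 0/1 for the occurrence
#'   model; `duration` or `tdr` for the Gaussian models).
#' @param fixed Character vector of fixed-effect column names.
#' @param interaction Optional length-2 character vector naming two fixed
#'   effects whose interaction is added (e.g. `c("temp_6h",
#'   "body_condition")`).
#' @param random Grouping column for the random intercept.
#' @param family `"gaussian"` or `"binomial"`.
#' @param reml Use REML for Gaussian fits (default `FALSE`, i.e. ML).
#' @param scale_numeric Z-score numeric predictors (default `TRUE`).
#' @return A `recess_fit` object; see [tidy.recess_fit()] and
#'   [glance.recess_fit()].
#' @export
fit_mixed_model <- function(data, response, fixed, interaction = NULL,
                            random = "nest_id",
                            family = c("gaussian", "binomial"),
                            reml = FALSE, scale_numeric = TRUE) {
  family <- match.arg(family)
  if (!is.null(interaction)) {
    stopifnot(length(interaction) == 2, all(interaction %in% fixed))
  }
  vars <- unique(c(response, fixed, random))
  missing <- setdiff(vars, names(data))
  if (length(missing) > 0) {
    abort(paste0("data lacks column(s): ", paste(missing, collapse = ", ")))
  }
  cc <- complete.cases(data[, vars])
  raw <- tibble::as_tibble(data[cc, vars])
  if (length(unique(raw[[random]])) < 2) {
    abort("need >= 2 grouping levels to fit a random intercept")
  }

  scaled <- raw
  scaling <- tibble::tibble(term = character(), center = numeric(), scale = numeric())
  if (scale_numeric) {
    for (v in fixed) {
      if (is.numeric(scaled[[v]])) {
        ctr <- mean(scaled[[v]])
        scl <- sd(scaled[[v]])
        if (scl == 0) scl <- 1
        scaled[[v]] <- (scaled[[v]] - ctr) / scl
        scaling <- dplyr::bind_rows(scaling,
          tibble::tibble(term = v, center = ctr, scale = scl))
      }
    }
  }

  rhs <- paste(c(fixed,
                 if (!is.null(interaction)) paste(interaction, collapse = ":"),
                 paste0("(1 | ", random, ")")),
               collapse = " + ")
  form <- as.formula(paste(response, "~", rhs))

  model <- withCallingHandlers(
    if (family == "binomial") {
      lme4::glmer(form, data = scaled, family = stats::binomial("logit"))
    } else {
      lmerTest::lmer(form, data = scaled, REML = reml)
    },
    warning = function(w) {
      if (grepl("singular", conditionMessage(w), ignore.case = TRUE)) {
        warn("random-intercept variance is (near) zero; fit retained")
        invokeRestart("muffleWarning")
      }
    },
    message = function(m) {
      if (grepl("singular", conditionMessage(m), ignore.case = TRUE)) {
        invokeRestart("muffleMessage")
      }
    }
  )
  conv <- model@optinfo$conv
  if (!is.null(conv$opt) && conv$opt != 0) {
    abort(paste0("optimizer failed to converge: ",
                 paste(unlist(conv$lme4$messages), collapse = "; ")))
  }

  fit <- structure(list(
    model = model, family = family, response = response, fixed = fixed,
    interaction = interaction, random = random, reml = reml,
    scaling = scaling, data_raw = raw, data_scaled = scaled,
    n_obs = nrow(raw), n_groups = length(unique(raw[[random]])),
    aic = AIC(model),
    singular = lme4::isSingular(model)
  ), class = "recess_fit")
  fit$r2 <- r2_nakagawa(fit)
  fit
}

#' @export
print.recess_fit <- function(x, ...) {
  cat(sprintf("recess_fit: %s ~ %s %s(%d obs, %d %s)\n",
              x$response, paste(x$fixed, collapse = " + "),
              if (!is.null(x$interaction))
                paste0("+ ", paste(x$interaction, collapse = ":"), " "),
              x$n_obs, x$n_groups, x$random))
  cat(sprintf("  family %s | AIC %.1f | R2 marginal %.3f conditional %.3f\n",
              x$family, x$aic, x$r2[["marginal"]], x$r2[["conditional"]]))
  invisible(x)
}

#' Marginal and conditional R-squared for mixed models
#'
#' Variance-partition coefficient of determination for GLMMs: the marginal
#' R2 is the fixed-effect variance over the total
#' (fixed + random-intercept + residual) variance on the link scale; the
#' conditional R2 adds the random-intercept variance to the numerator. For
#' a binomial-logit model the residual variance is the theoretical logistic
#' distribution variance pi^2 / 3.
#'
#' @param fit A `recess_fit` or a fitted `merMod`.
#' @return Named numeric vector `c(marginal =, conditional =)`.
#' @export
r2_nakagawa <- function(fit) {
  model <- if (inherits(fit, "recess_fit")) fit$model else fit
  family <- if (inherits(fit, "recess_fit")) {
    fit$family
  } else if (inherits(model, "glmerMod")) "binomial" else "gaussian"
  var_f <- var(predict(model, re.form = NA, type = "link"))
  var_r <- sum(vapply(lme4::VarCorr(model),
                      function(vc) sum(diag(vc)), numeric(1)))
  var_e <- if (family == "binomial") pi^2 / 3 else stats::sigma(model)^2
  tot <- var_f + var_r + var_e
  c(marginal = var_f / tot, conditional = (var_f + var_r) / tot)
}

#' Tidy coefficient table of a recess model fit
#'
#' Broom-style coefficient table. Estimates are on the Z-scored predictor
#' scale used for fitting; with `raw_units = TRUE` slopes are
#' back-transformed to raw predictor units (per degree C, per SMI gram,
#' per day), including the interaction slope. Gaussian fits report
#' Satterthwaite degrees of freedom and t-based p-values (via lmerTest);
#' binomial fits report Wald z statistics.
#'
#' @param x A `recess_fit`.
#' @param raw_units Back-transform estimates to raw predictor units.
#' @param ... Unused.
#' @exportS3Method generics::tidy
#' @export
tidy.recess_fit <- function(x, raw_units = FALSE, ...) {
  sm <- as.data.frame(summary(x$model)$coefficients)
  out <- tibble::tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    std.error = sm[, "Std. Error"]
  )
  if (x$family == "gaussian" && "df" %in% colnames(sm)) {
    out$df <- sm[, "df"]
    out$statistic <- sm[, "t value"]
    out$p.value <- sm[, "Pr(>|t|)"]
  } else {
    out$df <- Inf
    out$statistic <- sm[, "z value"]
    out$p.value <- sm[, "Pr(>|z|)"]
  }
  if (raw_units && nrow(x$scaling) > 0) {
    sc <- setNames(x$scaling$scale, x$scaling$term)
    fac <- vapply(out$term, function(tm) {
      parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
      prod(vapply(parts, function(p) sc[p] %||% 1, numeric(1)), na.rm = TRUE)
    }, numeric(1))
    fac[is.na(fac)] <- 1
    out$estimate <- unname(out$estimate / fac)
    out$std.error <- unname(out$std.error / fac)
  }
  out
}

#' One-line summary of a recess model fit
#'
#' @param x A `recess_fit`.
#' @param ... Unused.
#' @exportS3Method generics::glance
#' @export
glance.recess_fit <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n_obs, n_groups = x$n_groups,
    aic = x$aic, log_lik = as.numeric(stats::logLik(x$model)),
    sigma = stats::sigma(x$model),
    random_intercept_variance = sum(vapply(lme4::VarCorr(x$model),
                                           function(vc) sum(diag(vc)), numeric(1))),
    r2_marginal = x$r2[["marginal"]], r2_conditional = x$r2[["conditional"]],
    singular = x$singular
  )
}

#' @export
generics::tidy

#' @export
generics::glance

#' AIC optimization of the pre-recess temperature window
#'
#' Fits the same mixed model once per candidate averaging window of
#' pre-onset ground temperature (1, 2, 6, 12, 24 h), on the common
#' complete-case observation set, and compares the fits by AIC. Windows
#' within `delta_aic_support` (default 2) of the minimum are reported as
#' equally supported. AICs are only comparable on identical observations,
#' so rows missing any window covariate are removed before all fits; a
#' mismatch in n across fits is an error.
#'
#' @param data Covariate tibble with `temp_<w>h` columns.
#' @param response,fixed,interaction,random,family,reml As in
#'   [fit_mixed_model()]; `fixed` must *not* contain a temperature column
#'   (it is added per window). `interaction` may use the placeholder
#'   `"temp"` for the window column.
#' @param windows Candidate window lengths, hours.
#' @param delta_aic_support Delta-AIC defining equal support.
#' @return A `window_aic` list: `table` (window, aic, delta_aic, r2s,
#'   supported), `best_window`, `supported_windows`, `fits`.
#' @export
optimize_time_window <- function(data, response, fixed, windows = c(1, 2, 6, 12, 24),
                                 interaction = NULL, random = "nest_id",
                                 family = c("gaussian", "binomial"),
                                 reml = FALSE, delta_aic_support = 2) {
  family <- match.arg(family)
  temp_cols <- paste0("temp_", windows, "h")
  need <- unique(c(response, fixed, random, temp_cols))
  cc <- complete.cases(data[, need])
  dcc <- data[cc, , drop = FALSE]
  fits <- lapply(seq_along(windows), function(i) {
    tc <- temp_cols[i]
    ia <- if (!is.null(interaction)) sub("^temp$", tc, interaction)
    fit_mixed_model(dcc, response, c(fixed, tc), interaction = ia,
                    random = random, family = family, reml = reml)
  })
  names(fits) <- paste0(windows, "h")
  n <- vapply(fits, function(f) f$n_obs, numeric(1))
  if (length(unique(n)) != 1) {
    abort("window fits differ in n; AIC comparison invalid")
  }
  aic <- unname(vapply(fits, function(f) f$aic, numeric(1)))
  tab <- tibble::tibble(
    window_hours = windows, aic = aic, delta_aic = aic - min(aic),
    r2_marginal = unname(vapply(fits, function(f) f$r2[["marginal"]], numeric(1))),
    r2_conditional = unname(vapply(fits, function(f) f$r2[["conditional"]], numeric(1))),
    n_obs = unname(n)
  )
  tab$supported <- tab$delta_aic <= delta_aic_support
  structure(list(
    table = tab,
    best_window = windows[which.min(aic)],
    supported_windows = windows[tab$supported],
    fits = fits
  ), class = "window_aic")
}

#' @export
print.window_aic <- function(x, ...) {
  cat("Pre-recess temperature window optimization (AIC):\n")
  print(x$table)
  cat(sprintf("best window: %g h; equally supported: %s\n", x$best_window,
              paste(x$supported_windows, collapse = ", ")))
  invisible(x)
}

#' Johnson-Neyman bounds from interaction coefficients
#'
#' Closed-form moderator values at which the conditional slope
#' `s(m) = b_t + b_tm * m` changes significance: the real roots of
#' `s(m)^2 = t_crit^2 * Var[s(m)]` with
#' `Var[s(m)] = var_t + m^2 var_tm + 2 m cov_ttm`. When the roots are
#' complex the slope is significant everywhere or nowhere, decided by the
#' sign of the quadratic.
#'
#' @param b_t Slope of the focal predictor at moderator 0.
#' @param b_tm Interaction coefficient.
#' @param var_t,var_tm,cov_ttm Variances and covariance of the two
#'   coefficients.
#' @param t_crit Critical t (or z) value.
#' @return List with `lower`, `upper` (NA when absent) and `status`: one of
#'   `"two_roots"`, `"all_significant"`, `"none_significant"`.
#' @export
jn_bounds <- function(b_t, b_tm, var_t, var_tm, cov_ttm, t_crit) {
  A <- b_tm^2 - t_crit^2 * var_tm
  B <- 2 * (b_t * b_tm - t_crit^2 * cov_ttm)
  C <- b_t^2 - t_crit^2 * var_t
  disc <- B^2 - 4 * A * C
  if (abs(A) < 1e-300) {
    if (abs(B) < 1e-300) {
      status <- if (C > 0) "all_significant" else "none_significant"
      return(list(lower = NA_real_, upper = NA_real_, status = status))
    }
    root <- -C / B
    return(list(lower = root, upper = NA_real_, status = "one_root"))
  }
  if (disc < 0) {
    status <- if (A > 0) "all_significant" else "none_significant"
    return(list(lower = NA_real_, upper = NA_real_, status = status))
  }
  r <- sort(c((-B - sqrt(disc)) / (2 * A), (-B + sqrt(disc)) / (2 * A)))
  list(lower = r[1], upper = r[2], status = "two_roots")
}

# False-discovery-rate critical t over the observed moderator values:
# the smallest critical value T (not below the unadjusted one) such that
# the expected number of false positives among the |t_i| >= T tests,
# N * 2 * (1 - F_df(T)), is at most alpha * (number of discoveries).
fdr_critical_t <- function(t_stats, df, alpha = 0.05) {
  t_unadj <- qt(1 - alpha / 2, df)
  cand <- sort(unique(c(t_unadj, abs(t_stats))))
  N <- length(t_stats)
  for (T in cand) {
    R <- sum(abs(t_stats) >= T)
    if (R == 0) break
    ef <- N * 2 * (1 - pt(T, df))
    if (ef / R <= alpha) return(max(T, t_unadj))
  }
  max(cand)
}

#' Simple slopes and Johnson-Neyman interval for a fitted interaction
#'
#' Probes a temperature-by-moderator interaction: reports the conditional
#' temperature slope (in raw units, e.g. minutes per degree C) at chosen
#' moderator values (default: minimum, median and maximum observed body
#' condition), and the Johnson-Neyman moderator values where the slope
#' stops being significant at level `alpha`. Two sets of bounds are always
#' returned: with the nominal critical value, and with a critical value
#' inflated to control the false discovery rate across the observed
#' moderator values (both are reported since multiplicity control shifts
#' the boundary).
#'
#' Degrees of freedom: Gaussian fits use the Satterthwaite approximation
#' per probed slope (residual df for the JN quadratic, flagged in the
#' output); binomial fits use Wald z.
#'
#' @param fit A `recess_fit` containing the interaction.
#' @param temp Name of the focal (temperature) predictor.
#' @param moderator Name of the moderating predictor (body condition).
#' @param probe_values Raw-scale moderator values at which to report
#'   conditional slopes; default `min`, `median`, `max` of the data.
#' @param alpha Significance level.
#' @return A `jn_result` list: `slopes` tibble, `jn` tibble (one row per
#'   adjustment), `alpha`, `df`, `df_method`.
#' @export
simple_slopes_jn <- function(fit, temp, moderator, probe_values = NULL,
                             alpha = 0.05) {
  if (is.null(fit$interaction)) abort("fit contains no interaction term")
  fe <- lme4::fixef(fit$model)
  vc <- as.matrix(vcov(fit$model))
  ia_name <- intersect(c(paste(temp, moderator, sep = ":"),
                         paste(moderator, temp, sep = ":")), names(fe))
  if (length(ia_name) != 1 || !temp %in% names(fe)) {
    abort(sprintf("fit has no %s x %s interaction", temp, moderator))
  }
  b_t <- fe[[temp]]
  b_tm <- fe[[ia_name]]
  var_t <- vc[temp, temp]
  var_tm <- vc[ia_name, ia_name]
  cov_ttm <- vc[temp, ia_name]

  sc <- setNames(split(fit$scaling, seq_len(nrow(fit$scaling))), fit$scaling$term)
  ctr <- function(v) if (v %in% fit$scaling$term)
    fit$scaling$center[fit$scaling$term == v] else 0
  scl <- function(v) if (v %in% fit$scaling$term)
    fit$scaling$scale[fit$scaling$term == v] else 1

  mod_raw <- fit$data_raw[[moderator]]
  if (is.null(probe_values)) {
    probe_values <- c(min = min(mod_raw), median = median(mod_raw),
                      max = max(mod_raw))
  }
  mz <- (probe_values - ctr(moderator)) / scl(moderator)
  slope_z <- b_t + b_tm * mz
  se_z <- sqrt(var_t + mz^2 * var_tm + 2 * mz * cov_ttm)

  p <- length(fe)
  df_resid <- fit$n_obs - p
  gaussian <- fit$family == "gaussian"
  df_probe <- rep(if (gaussian) df_resid else Inf, length(mz))
  df_method <- if (gaussian) "residual" else "wald_z"
  if (gaussian) {
    df_try <- vapply(mz, function(m) {
      L <- setNames(rep(0, p), names(fe))
      L[temp] <- 1
      L[ia_name] <- m
      tryCatch(lmerTest::contest1D(fit$model, L, ddf = "Satterthwaite")$df,
               error = function(e) NA_real_)
    }, numeric(1))
    if (!any(is.na(df_try))) {
      df_probe <- df_try
      df_method <- "satterthwaite"
    }
  }
  tstat <- slope_z / se_z
  slopes <- tibble::tibble(
    moderator_value = unname(as.numeric(probe_values)),
    label = names(probe_values) %||% rep("", length(probe_values)),
    slope = unname(slope_z / scl(temp)),
    se = unname(se_z / scl(temp)),
    statistic = unname(tstat), df = unname(df_probe),
    p.value = unname(2 * pt(-abs(tstat), df_probe))
  )

  # JN quadratic solved on the z scale, bounds back-transformed
  df_jn <- if (gaussian) df_resid else Inf
  mz_obs <- (mod_raw - ctr(moderator)) / scl(moderator)
  t_obs <- (b_t + b_tm * mz_obs) /
    sqrt(var_t + mz_obs^2 * var_tm + 2 * mz_obs * cov_ttm)
  t_unadj <- qt(1 - alpha / 2, df_jn)
  t_fdr <- fdr_critical_t(t_obs, df_jn, alpha)
  back <- function(z) ctr(moderator) + scl(moderator) * z
  jn_row <- function(adjust, tc) {
    b <- jn_bounds(b_t, b_tm, var_t, var_tm, cov_ttm, tc)
    tibble::tibble(adjustment = adjust, t_crit = tc,
                   lower = back(b$lower), upper = back(b$upper),
                   status = b$status)
  }
  structure(list(
    slopes = slopes,
    jn = dplyr::bind_rows(jn_row("unadjusted", t_unadj), jn_row("fdr", t_fdr)),
    alpha = alpha, df = df_jn, df_method = df_method,
    temp = temp, moderator = moderator
  ), class = "jn_result")
}

#' @export
print.jn_result <- function(x, ...) {
  cat(sprintf("Simple slopes of %s conditional on %s:\n", x$temp, x$moderator))
  print(x$slopes)
  cat("Johnson-Neyman bounds (raw moderator units):\n")
  print(x$jn)
  invisible(x)
}

#' Choose between interaction and no-interaction specifications
#'
#' Fits (or accepts) the model with and without the temperature-by-body
#' condition interaction and retains the one with the higher marginal
#' R-squared; a tie goes to the simpler, no-interaction model. Marginal
#' R-squared is compared at `r2_digits` decimals (default 2, the precision
#' at which such values are reported), so a vanishing improvement from the
#' extra parameter does not pull in the interaction. Both AICs and
#' R-squared values are reported for transparency.
#'
#' @param fit_with,fit_without `recess_fit` objects for the two
#'   specifications.
#' @param r2_digits Decimals at which marginal R-squared is compared.
#' @return List `chosen` (a `recess_fit`), `selected` (`"with"` /
#'   `"without"`), `comparison` tibble.
#' @export
select_interaction_model <- function(fit_with, fit_without, r2_digits = 2) {
  r2w <- fit_with$r2[["marginal"]]
  r2o <- fit_without$r2[["marginal"]]
  selected <- if (round(r2w, r2_digits) > round(r2o, r2_digits)) "with" else "without"
  comparison <- tibble::tibble(
    spec = c("with_interaction", "without_interaction"),
    aic = c(fit_with$aic, fit_without$aic),
    r2_marginal = c(r2w, r2o),
    r2_conditional = c(fit_with$r2[["conditional"]], fit_without$r2[["conditional"]])
  )
  list(chosen = if (selected == "with") fit_with else fit_without,
       selected = selected, comparison = comparison)
}

#' Average relative change in extended-recess probability per degree
#'
#' Summarizes the occurrence GLMM as the average, over the observed
#' temperature range, of the relative change in the predicted probability
#' of an extended recess per +1 degree C (other covariates at their means,
#' random effects at zero). `scale = "odds"` instead reports the constant
#' odds change per degree, `exp(beta_per_degC) - 1`.
#'
#' @param fit Occurrence `recess_fit` (binomial).
#' @param temp Temperature predictor name.
#' @param scale `"probability"` or `"odds"`.
#' @return Average proportional change per degree (e.g. -0.20 for a 20%
#'   decrease).
#' @export
prob_change_per_degree <- function(fit, temp, scale = c("probability", "odds")) {
  scale <- match.arg(scale)
  if (fit$family != "binomial") abort("occurrence summary needs a binomial fit")
  fe <- lme4::fixef(fit$model)
  s <- fit$scaling
  scl <- function(v) if (v %in% s$term) s$scale[s$term == v] else 1
  beta_raw <- fe[[temp]] / scl(temp)
  if (scale == "odds") return(exp(beta_raw) - 1)
  tr <- range(fit$data_raw[[temp]])
  grid <- seq(floor(tr[1]), ceiling(tr[2]) - 1)
  eta0 <- fe[["(Intercept)"]] # other scaled covariates at 0 = their means
  zt <- function(x) (x - s$center[s$term == temp]) / scl(temp)
  p <- plogis(eta0 + fe[[temp]] * zt(grid))
  p1 <- plogis(eta0 + fe[[temp]] * zt(grid + 1))
  mean(p1 / p - 1)
}
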