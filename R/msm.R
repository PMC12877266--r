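#' Fit a weighted binomial marginal structural model
#'
#' Regresses a binary outcome on the exposure plus the other food groups (the
#' all-component diet), weighted by the combined IPW weights, so that
#' confounders never enter the outcome model. Food intakes enter the linear
#' predictor in units of 100 g/d, so each coefficient reads "per 100 g/d".
#' Links:
#' * `"logit"`: weighted quasi-binomial fit (the default for reporting);
#' * `"identity"`: weighted linear probability model, for which marginal
#'   contrasts have closed forms.
#'
#' Both the model-based and the robust (HC0 sandwich) coefficient covariance
#' are retained; interval construction uses the robust one.
#'
#' @param data analysis rows (tibble). Rows with a missing outcome or missing
#'   weight are excluded (and counted).
#' @param outcome name of the 0/1 outcome column.
#' @param exposure name of the exposure food-group column (g/d).
#' @param foods other food-group columns held in the model (g/d).
#' @param weights `NULL` (unit weights), a numeric vector, a weight column
#'   name, or a `weight_set` (its `w`, joined by `participant_id`).
#' @param link `"logit"` or `"identity"`.
#' @return an `msm_fit` object.
#' @export
fit_msm <- function(data, outcome, exposure, foods, weights = NULL,
                    link = c("logit", "identity")) {
  link <- match.arg(link)
  terms <- c(exposure, foods)
  assert_cols(data, c(outcome, terms), "analysis table")
  w <- resolve_weights(data, weights)
  if (is.null(w)) w <- rep(1, nrow(data))
  y <- data[[outcome]]
  keep <- !is.na(y) & !is.na(w)
  if (!all(y[keep] %in% c(0, 1))) {
    abort_validation(sprintf("outcome '%s' must be binary 0/1", outcome))
  }
  if (any(w[keep] <= 0)) abort_validation("weights must be positive")
  md <- data[keep, terms, drop = FALSE] / 100
  md$.y <- y[keep]
  md$.w <- w[keep]
  fml <- reformulate(sprintf("`%s`", terms), ".y")
  if (link == "identity") {
    fit <- lm(fml, data = md, weights = .w)
  } else {
    fit <- suppressWarnings(
      glm(fml, family = quasibinomial("logit"), data = md, weights = .w,
          control = list(maxit = 100))
    )
    if (!fit$converged) {
      abort_estimation("MSM did not converge; check weights and separation")
    }
    mu <- fit$fitted.values
    if (any(mu < 1e-10 | mu > 1 - 1e-10)) {
      abort_estimation("complete separation in the MSM fit")
    }
  }
  structure(
    list(
      fit = fit, link = link, outcome = outcome, exposure = exposure,
      foods = foods, terms = terms,
      X = model.matrix(fit), w = md$.w, n = sum(keep),
      n_dropped = sum(!keep),
      vcov_model = vcov(fit),
      vcov_robust = sandwich::vcovHC(fit, type = "HC0")
    ),
    class = "msm_fit"
  )
}

#' @export
print.msm_fit <- function(x, ...) {
  cat(sprintf("<msm_fit> outcome '%s', exposure '%s', link %s, n = %d\n",
              x$outcome, x$exposure, x$link, x$n))
  print(round(coef(x$fit), 5))
  invisible(x)
}

#' Tidy an MSM fit
#'
#' @param x an `msm_fit`.
#' @param robust use the sandwich covariance for standard errors (default).
#' @param ... unused.
#' @return tibble: term, estimate (per 100 g/d), std.error, statistic, p.value.
#' @export
tidy.msm_fit <- function(x, robust = TRUE, ...) {
  b <- coef(x$fit)
  V <- if (robust) x$vcov_robust else x$vcov_model
  se <- sqrt(diag(V))
  tibble::tibble(
    term = names(b), estimate = unname(b), std.error = unname(se),
    statistic = unname(b / se),
    p.value = 2 * pnorm(-abs(unname(b / se)))
  )
}

#' @export
glance.msm_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_dropped = x$n_dropped, link = x$link,
    ess = effective_sample_size(x$w),
    outcome = x$outcome, exposure = x$exposure
  )
}

# Coefficient name in the fitted model for a food term.
term_coef_name <- function(fit, term) {
  nm <- colnames(fit$X)
  hit <- nm[nm == term | nm == sprintf("`%s`", term)]
  if (length(hit) != 1) {
    abort_validation(sprintf("'%s' is not a term of the fitted MSM", term))
  }
  hit
}

# Marginal-standardized ACE of adding delta g/d to `term`, as a function of the
# coefficient vector; for the identity link this is the linear functional
# (delta/100) * beta_term (exactly), so the contrast vector is returned
# instead. The standardization population is the weighted analysis sample at
# its observed covariate values.
ace_functional <- function(fit, add = NULL, subtract = NULL, delta = 100) {
  cn <- colnames(fit$X)
  contrast <- setNames(rep(0, length(cn)), cn)
  for (t in add) {
    contrast[term_coef_name(fit, t)] <-
      contrast[term_coef_name(fit, t)] + delta / 100
  }
  for (t in subtract) {
    contrast[term_coef_name(fit, t)] <-
      contrast[term_coef_name(fit, t)] - delta / 100
  }
  if (fit$link == "identity") {
    return(list(kind = "linear", contrast = contrast))
  }
  X <- fit$X
  w <- fit$w
  shift <- function(terms) {
    Xs <- X
    for (t in terms) {
      Xs[, term_coef_name(fit, t)] <- Xs[, term_coef_name(fit, t)] + delta / 100
    }
    Xs
  }
  Xa <- if (length(add)) shift(add) else NULL
  Xs <- if (length(subtract)) shift(subtract) else NULL
  f <- function(beta) {
    p0 <- plogis(drop(X %*% beta))
    val <- 0
    if (!is.null(Xa)) val <- val + wtd_mean(plogis(drop(Xa %*% beta)) - p0, w)
    if (!is.null(Xs)) val <- val - wtd_mean(plogis(drop(Xs %*% beta)) - p0, w)
    val
  }
  list(kind = "function", f = f)
}

#' Parametric confidence interval for an ACE functional
#'
#' Default method draws `n_draws` coefficient vectors from a multivariate
#' normal centred at the estimates with the robust covariance, recomputes the
#' functional per draw and takes the central quantile interval. The
#' delta-method alternative uses the analytic SE for linear functionals and a
#' central-difference gradient otherwise.
#'
#' @param fit an `msm_fit`.
#' @param functional a named contrast vector over coefficients (linear
#'   functional) or a function of the coefficient vector.
#' @param level confidence level.
#' @param method `"simulation"` (default) or `"delta"`.
#' @param n_draws simulation draws.
#' @param vcov `"robust"` (default) or `"model"`.
#' @return list: `low`, `high`, `method`. Simulation draws consume the current
#'   RNG stream; seed outside for reproducibility.
#' @export
parametric_ci <- function(fit, functional, level = 0.95,
                          method = c("simulation", "delta"),
                          n_draws = 10000, vcov = c("robust", "model")) {
  method <- match.arg(method)
  vcov <- match.arg(vcov)
  V <- if (vcov == "robust") fit$vcov_robust else fit$vcov_model
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    abort_estimation("coefficient covariance is not positive semi-definite")
  }
  b <- coef(fit$fit)
  alpha <- (1 - level) / 2
  is_linear <- is.numeric(functional)
  if (method == "delta") {
    if (is_linear) {
      cvec <- functional[names(b)]
      est <- sum(cvec * b)
      se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    } else {
      est <- functional(b)
      h <- pmax(abs(b), 1) * 1e-6
      grad <- purrr::map_dbl(seq_along(b), function(j) {
        bp <- b; bm <- b
        bp[j] <- bp[j] + h[j]; bm[j] <- bm[j] - h[j]
        (functional(bp) - functional(bm)) / (2 * h[j])
      })
      se <- sqrt(drop(t(grad) %*% V %*% grad))
    }
    z <- qnorm(1 - alpha)
    return(list(low = est - z * se, high = est + z * se, method = "delta"))
  }
  draws <- MASS::mvrnorm(n_draws, mu = b, Sigma = V)
  if (is_linear) {
    qs <- drop(draws %*% functional[names(b)])
  } else {
    # chunk the draws so the row-by-draw prediction matrices stay small
    chunks <- split(seq_len(n_draws), ceiling(seq_len(n_draws) / 250))
    qs <- unlist(purrr::map(chunks, function(idx) {
      apply(draws[idx, , drop = FALSE], 1, functional)
    }), use.names = FALSE)
  }
  list(low = quantile7(qs, alpha), high = quantile7(qs, 1 - alpha),
       method = "simulation")
}

effect_row <- function(fit, estimand, food, ace, ci, delta, level,
                       n_clamped = 0L) {
  slope <- unname(coef(fit$fit)[term_coef_name(fit, fit$exposure)])
  tibble::tibble(
    outcome = fit$outcome, exposure = fit$exposure, estimand = estimand,
    food = food, delta = delta,
    ace = ace, ci_low = ci$low, ci_high = ci$high, level = level,
    slope_per_100g = slope, n = fit$n, ci_method = ci$method, link = fit$link,
    n_clamped = n_clamped
  )
}

#' Average causal effect of adding `delta` g/d of the exposure
#'
#' Marginal standardization over the weighted analysis sample: the weighted
#' mean of the model-predicted outcome probability at observed intakes plus
#' `delta` on the exposure, minus the prediction at observed intakes. Under the
#' identity link this equals `delta/100 * beta_exposure` exactly; identity-link
#' predictions that leave \[0, 1\] after the shift are counted and reported
#' (`n_clamped`, with a warning) but the estimate is not altered.
#'
#' @param fit an `msm_fit`.
#' @param delta increment in g/d (default 100).
#' @param level confidence level.
#' @param ci_method `"simulation"` (default) or `"delta"`.
#' @param n_draws simulation draws for the interval.
#' @return an `effect_estimate` tibble row: ACE (risk difference, probability
#'   scale), CI, slope per 100 g/d, n, method tags.
#' @export
ace_addition <- function(fit, delta = 100, level = 0.95,
                         ci_method = c("simulation", "delta"),
                         n_draws = 10000) {
  ci_method <- match.arg(ci_method)
  fn <- ace_functional(fit, add = fit$exposure, delta = delta)
  b <- coef(fit$fit)
  n_clamped <- 0L
  if (fn$kind == "linear") {
    ace <- sum(fn$contrast * b)
    p1 <- drop(fit$X %*% b) + ace
    n_clamped <- sum(p1 < 0 | p1 > 1)
    if (n_clamped > 0) {
      rlang::warn(sprintf(
        "%d identity-link predicted probabilities outside [0, 1] after the %g g/d shift",
        n_clamped, delta))
    }
    ci <- parametric_ci(fit, fn$contrast, level, ci_method, n_draws)
  } else {
    ace <- fn$f(b)
    ci <- parametric_ci(fit, fn$f, level, ci_method, n_draws)
  }
  out <- effect_row(fit, "addition", NA_character_, ace, ci, delta, level,
                    n_clamped)
  structure(out, class = c("effect_estimate", class(out)))
}

#' Average causal effect of substituting a food with the exposure
#'
#' Difference of two addition effects from the same all-component fit:
#' `ACE_add(exposure) - ACE_add(food)`. Sign convention (printed in every
#' output): positive means replacing `delta` g/d of `food` with the exposure
#' *raises* the outcome risk. Under the identity link this equals
#' `delta/100 * (beta_exposure - beta_food)` exactly. Intervals come from joint
#' coefficient draws (or the joint delta method), so the correlation between
#' the two addition effects is respected.
#'
#' @inheritParams ace_addition
#' @param food the substituted food group; must be a covariate of the fit.
#' @return an `effect_estimate` tibble row.
#' @export
ace_substitution <- function(fit, food, delta = 100, level = 0.95,
                             ci_method = c("simulation", "delta"),
                             n_draws = 10000) {
  ci_method <- match.arg(ci_method)
  if (!food %in% fit$foods) {
    abort_validation(sprintf(
      "substitution food '%s' is not a covariate of the fitted MSM", food))
  }
  fn <- ace_functional(fit, add = fit$exposure, subtract = food, delta = delta)
  b <- coef(fit$fit)
  if (fn$kind == "linear") {
    ace <- sum(fn$contrast * b)
    ci <- parametric_ci(fit, fn$contrast, level, ci_method, n_draws)
  } else {
    ace <- fn$f(b)
    ci <- parametric_ci(fit, fn$f, level, ci_method, n_draws)
  }
  out <- effect_row(fit, "substitution", food, ace, ci, delta, level)
  structure(out, class = c("effect_estimate", class(out)))
}

#' Run the full addition/substitution effect grid
#'
#' End-to-end estimation on a cohort that already carries coded binary outcome
#' columns: per exposure, fit stabilized treatment weights on the weighting
#' set, censoring weights once, combine and truncate, fit the weighted MSM per
#' outcome on the followed rows, and compute the addition effect plus one
#' substitution effect per substitution food. Subtype dairy exposures keep the
#' complementary dairy (`dairy_other = dairy_total - exposure`) in the model so
#' the all-component diet stays represented.
#'
#' @param cohort cohort tibble including item intakes (aggregated internally),
#'   covariates, follow-up indicator and coded outcome columns.
#' @param outcomes character vector of binary 0/1 outcome column names.
#' @param exposures dairy exposure columns (defaults to all six aggregates).
#' @param substitution_foods foods substituted with the exposure.
#' @param confounders treatment-weight confounder set.
#' @param censoring_covariates censoring-weight covariate set.
#' @param delta increment (g/d).
#' @param percentile weight-truncation percentile.
#' @param link MSM link.
#' @param ci_method,n_draws interval method.
#' @param level confidence level.
#' @param followed follow-up indicator column.
#' @param map food-group map for aggregation.
#' @param seed integer seed for the interval draws.
#' @return an `effect_table` tibble (one `effect_estimate` row per estimand)
#'   with percent-scale columns `ace_pct`, `ci_low_pct`, `ci_high_pct` added.
#' @export
run_full_analysis <- function(cohort,
                              outcomes,
                              exposures = dairy_group_names(),
                              substitution_foods = c("meat", "fish_seafood",
                                                     "eggs", "vegetables",
                                                     "fruits"),
                              confounders = default_confounders(),
                              censoring_covariates = default_censoring_covariates(),
                              delta = 100, percentile = 99.5,
                              link = c("logit", "identity"),
                              ci_method = c("simulation", "delta"),
                              n_draws = 10000, level = 0.95,
                              followed = "followed",
                              map = default_food_group_map(),
                              seed = 1) {
  link <- match.arg(link)
  ci_method <- match.arg(ci_method)
  cohort <- add_food_groups(cohort, map = map)
  assert_cols(cohort, c(outcomes, exposures, substitution_foods, confounders,
                        censoring_covariates, followed), "cohort")
  other_foods <- c("vegetables", "fruits", "fish_seafood", "meat", "eggs",
                   "grains", "alcohol", "sugary_processed", "high_fat")
  cw <- fit_censoring_weights(cohort, censoring_covariates, followed = followed)
  withr::with_seed(seed, {
    rows <- purrr::map_dfr(exposures, function(expo) {
      dat <- cohort
      foods <- intersect(other_foods, names(dat))
      if (expo != "dairy_total") {
        dat$dairy_other <- dat$dairy_total - dat[[expo]]
        foods <- c("dairy_other", foods)
      }
      tw <- fit_treatment_weights(dat, expo, confounders)
      ws <- combine_weights(tw, cw, percentile = percentile)
      purrr::map_dfr(outcomes, function(oc) {
        fit <- fit_msm(dat, oc, expo, foods, weights = ws, link = link)
        dplyr::bind_rows(
          ace_addition(fit, delta, level, ci_method, n_draws),
          purrr::map_dfr(substitution_foods, function(f) {
            ace_substitution(fit, f, delta, level, ci_method, n_draws)
          })
        )
      })
    })
  })
  rows$ace_pct <- 100 * rows$ace
  rows$ci_low_pct <- 100 * rows$ci_low
  rows$ci_high_pct <- 100 * rows$ci_high
  structure(rows, class = c("effect_table", class(rows)),
            sign_convention = paste(
              "positive = replacing the substituted food with the exposure",
              "raises outcome risk"))
}

#' Default confounder set
#'
#' The baseline covariates adjusted for in the treatment-weight model: age
#' group, sex, education, occupation, BMI category, smoking, past
#' cardiovascular event, hypertension, diabetes, depression history, income
#' tertile and physical-activity tertile.
#' @return character vector of column names.
#' @export
default_confounders <- function() {
  c("age_group", "sex", "education", "occupation", "bmi_category", "smoking",
    "past_cvd", "hypertension", "diabetes", "depression", "income_tertile",
    "pa_tertile")
}

#' Default censoring-model covariates
#'
#' Covariates of the loss-to-follow-up model: age group, sex, occupation, BMI
#' category, smoking, past cardiovascular events, hypertension and diabetes.
#' @return character vector of column names.
#' @export
default_censoring_covariates <- function() {
  c("age_group", "sex", "occupation", "bmi_category", "smoking", "past_cvd",
    "hypertension", "diabetes")
}

#' Forest plot of an effect table
#'
#' @param object an `effect_table` from [run_full_analysis()].
#' @param ... unused.
#' @return a ggplot of percent-scale ACEs with confidence intervals.
#' @export
autoplot.effect_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$label <- ifelse(df$estimand == "addition", "addition",
                     paste0("vs ", df$food))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ace_pct, y = .data$label)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low_pct, xmax = .data$ci_high_pct),
      height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::facet_grid(exposure ~ outcome) +
    ggplot2::labs(x = "risk difference per 100 g/d (%)", y = NULL) +
    ggplot2::theme_minimal()
}
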