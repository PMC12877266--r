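#' Stabilized treatment weights for a continuous exposure
#'
#' Gaussian density-ratio weights `SW_A = f(A) / f(A | L)`: the numerator is a
#' normal density with the marginal mean and SD of the exposure, the
#' denominator a normal density whose mean comes from a linear model of the
#' exposure on the confounders and whose SD is that model's residual SD. The
#' models are fitted on the rows with complete exposure and confounders (the
#' eligible-for-weighting set); rows with incomplete confounders are excluded
#' from fitting but still receive a weight by the chosen fallback:
#' `"weight1"` (default) assigns weight 1 with a flag, `"drop"` returns `NA`.
#' (A "marginal-only" fallback is not a distinct mode: under stabilization it
#' equals weight 1.)
#'
#' @param data cohort tibble; must contain `participant_id`, the exposure and
#'   the confounders. Missing exposure is an error — a participant without an
#'   exposure measurement is not in the weighting set.
#' @param exposure name of the continuous exposure column (g/d).
#' @param confounders character vector of confounder column names.
#' @param na_action fallback for incomplete-confounder rows.
#' @return a `weight_set` tibble: `participant_id`, `sw_a`, `incomplete`;
#'   metadata (model formula, numerator mean/SD, residual SD) in
#'   `attr(, "meta")`.
#' @export
fit_treatment_weights <- function(data, exposure, confounders,
                                  na_action = c("weight1", "drop")) {
  na_action <- match.arg(na_action)
  assert_cols(data, c("participant_id", exposure, confounders), "cohort")
  # with no confounders the numerator and denominator models coincide and
  # every weight is exactly 1; kept as a genuine code path, not special-cased
  a <- data[[exposure]]
  if (any(is.na(a))) {
    abort_validation(sprintf("exposure '%s' has missing values", exposure))
  }
  cc <- if (length(confounders) == 0) rep(TRUE, nrow(data))
        else stats::complete.cases(data[, confounders, drop = FALSE])
  fit_data <- data[cc, , drop = FALSE]
  fml <- if (length(confounders) == 0) reformulate("1", exposure)
         else reformulate(confounders, exposure)
  fit <- lm(fml, data = fit_data)
  s_den <- sigma(fit)
  if (!is.finite(s_den) || s_den <= 1e-12) {
    abort_estimation("treatment weight model has zero residual SD")
  }
  m_num <- mean(a[cc])
  s_num <- sd(a[cc])
  sw <- rep(NA_real_, nrow(data))
  mu <- predict(fit, newdata = data[cc, , drop = FALSE])
  sw[cc] <- dnorm(a[cc], m_num, s_num) / dnorm(a[cc], mu, s_den)
  if (any(!is.finite(sw[cc]))) {
    bad <- data$participant_id[cc][!is.finite(sw[cc])]
    abort_estimation(sprintf(
      "non-finite treatment weight for participant(s): %s",
      paste(head(bad, 5), collapse = ", ")))
  }
  sw[!cc] <- if (na_action == "weight1") 1 else NA_real_
  new_weight_set(
    tibble::tibble(participant_id = data$participant_id, sw_a = sw,
                   incomplete_a = !cc),
    meta = list(
      type = "treatment", exposure = exposure, confounders = confounders,
      numerator = "marginal normal density of the exposure",
      num_mean = m_num, num_sd = s_num, resid_sd = s_den,
      n_fit = sum(cc), na_action = na_action
    )
  )
}

#' Stabilized censoring weights for loss to follow-up
#'
#' `SW_C = P(C = 1) / P(C = 1 | L)` with the denominator from a logistic model
#' of remaining under follow-up on baseline covariates, fitted on the eligible
#' population. Followed participants get a weight; non-followed participants
#' contribute to the model but receive `NA` (they have no follow-up outcome to
#' weight). If nobody is lost to follow-up all weights are exactly 1.
#'
#' @param data cohort tibble with `participant_id`, the follow-up indicator and
#'   the covariates.
#' @param covariates censoring-model covariates.
#' @param followed name of the 0/1 follow-up indicator column.
#' @inheritParams fit_treatment_weights
#' @return a `weight_set` tibble: `participant_id`, `sw_c`, `incomplete_c`.
#' @export
fit_censoring_weights <- function(data, covariates, followed = "followed",
                                  na_action = c("weight1", "drop")) {
  na_action <- match.arg(na_action)
  assert_cols(data, c("participant_id", followed, covariates), "cohort")
  C <- data[[followed]]
  if (any(is.na(C)) || !all(C %in% c(0, 1))) {
    abort_validation("follow-up indicator must be observed 0/1 for all rows")
  }
  sw <- rep(NA_real_, nrow(data))
  if (all(C == 1)) {
    sw[] <- 1
    return(new_weight_set(
      tibble::tibble(participant_id = data$participant_id, sw_c = sw,
                     incomplete_c = FALSE),
      meta = list(type = "censoring", covariates = covariates,
                  marginal_p = 1, note = "no dropout; all weights 1")
    ))
  }
  cc <- stats::complete.cases(data[, covariates, drop = FALSE])
  fit_data <- data[cc, , drop = FALSE]
  fit_data$.C <- C[cc]
  fit <- glm(reformulate(covariates, ".C"), family = binomial(),
             data = fit_data)
  if (!fit$converged) {
    abort_estimation("censoring weight model did not converge")
  }
  p_hat <- predict(fit, newdata = data[cc, , drop = FALSE], type = "response")
  if (any(p_hat < 1e-8 | p_hat > 1 - 1e-8)) {
    abort_estimation(paste0(
      "(near-)perfect separation in the censoring model; ",
      "coarsen the covariates and refit"))
  }
  p_marg <- mean(C[cc])
  idx <- cc & C == 1
  sw[idx] <- p_marg / p_hat[C[cc] == 1]
  sw[!cc & C == 1] <- if (na_action == "weight1") 1 else NA_real_
  new_weight_set(
    tibble::tibble(participant_id = data$participant_id, sw_c = sw,
                   incomplete_c = !cc),
    meta = list(type = "censoring", covariates = covariates,
                marginal_p = p_marg, n_fit = sum(cc), na_action = na_action)
  )
}

#' Truncate weights at a percentile cap
#'
#' Values above the cap are set to the cap; values at or below pass unchanged.
#' The cap is the given percentile of the supplied weights as an *order
#' statistic* (inverse-CDF, type-1 quantile): an interpolated cap would move
#' every time it is recomputed on already-capped weights, whereas the
#' order-statistic cap makes truncation exactly idempotent.
#'
#' @param w positive finite weights (NAs pass through and are ignored for the
#'   cap).
#' @param percentile cap percentile (default 99.5).
#' @return truncated weights with the cap in `attr(, "cap")`.
#' @export
truncate_weights <- function(w, percentile = 99.5) {
  obs <- w[!is.na(w)]
  if (length(obs) == 0) abort_validation("no weights to truncate")
  if (any(obs <= 0) || any(!is.finite(obs))) {
    abort_validation("weights must be positive and finite")
  }
  cap <- stats::quantile(obs, percentile / 100, type = 1, names = FALSE)
  out <- pmin(w, cap)
  attr(out, "cap") <- cap
  out
}

#' Combine treatment and censoring weights
#'
#' The final analysis weight is the product of the (optionally pre-truncated)
#' stabilized treatment and censoring weights, truncated again at the same
#' percentile. Only followed participants carry a combined weight.
#'
#' @param tw treatment `weight_set` from [fit_treatment_weights()].
#' @param cw censoring `weight_set` from [fit_censoring_weights()].
#' @param percentile truncation percentile (default 99.5).
#' @param truncate_components truncate `sw_a` and `sw_c` before multiplying
#'   (default `TRUE`; the product is always truncated).
#' @return a `weight_set` tibble: `participant_id`, `sw_a`, `sw_c`, `w`,
#'   incompleteness flags; caps and summaries in `attr(, "meta")`.
#' @export
combine_weights <- function(tw, cw, percentile = 99.5,
                            truncate_components = TRUE) {
  if (!setequal(tw$participant_id, cw$participant_id)) {
    abort_validation("treatment and censoring weight sets cover different ids")
  }
  cw <- cw[match(tw$participant_id, cw$participant_id), ]
  a <- tw$sw_a
  cc <- cw$sw_c
  cap_a <- cap_c <- NA_real_
  if (truncate_components) {
    a <- truncate_weights(a, percentile)
    cap_a <- attr(a, "cap")
    cc <- truncate_weights(cc, percentile)
    cap_c <- attr(cc, "cap")
  }
  w <- as.numeric(a) * as.numeric(cc)
  w <- truncate_weights(w, percentile)
  cap_w <- attr(w, "cap")
  out <- tibble::tibble(
    participant_id = tw$participant_id,
    sw_a = as.numeric(a), sw_c = as.numeric(cc), w = as.numeric(w),
    incomplete_a = tw$incomplete_a %||% FALSE,
    incomplete_c = cw$incomplete_c %||% FALSE
  )
  new_weight_set(out, meta = c(
    attr(tw, "meta")[c("exposure", "confounders", "num_mean", "num_sd",
                       "resid_sd")],
    list(percentile = percentile, truncate_components = truncate_components,
         cap_a = cap_a, cap_c = cap_c, cap_w = cap_w,
         ess = effective_sample_size(out$w))
  ))
}

new_weight_set <- function(df, meta) {
  structure(df, meta = meta, class = c("weight_set", class(df)))
}

#' @export
print.weight_set <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("<weight_set> %d participants\n", nrow(x)))
  NextMethod()
  invisible(x)
}

#' Summary diagnostics of a weight set
#'
#' @param x a `weight_set`.
#' @param ... unused.
#' @return one-row tibble: n, effective sample size and mean/min/max of each
#'   weight column present, plus the truncation caps when recorded.
#' @export
glance.weight_set <- function(x, ...) {
  meta <- attr(x, "meta") %||% list()
  wcol <- if ("w" %in% names(x)) x$w else x[[intersect(c("sw_a", "sw_c"),
                                                       names(x))[1]]]
  out <- tibble::tibble(
    n = nrow(x),
    n_weighted = sum(!is.na(wcol)),
    ess = effective_sample_size(wcol),
    mean_w = mean(wcol, na.rm = TRUE),
    min_w = min(wcol, na.rm = TRUE),
    max_w = max(wcol, na.rm = TRUE)
  )
  if ("sw_a" %in% names(x)) out$mean_sw_a <- mean(x$sw_a, na.rm = TRUE)
  if ("sw_c" %in% names(x)) out$mean_sw_c <- mean(x$sw_c, na.rm = TRUE)
  for (f in c("cap_a", "cap_c", "cap_w")) {
    if (!is.null(meta[[f]])) out[[f]] <- meta[[f]]
  }
  out
}

#' Histogram of combined weights
#'
#' @param object a `weight_set`.
#' @param bins histogram bins.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.weight_set <- function(object, bins = 40, ...) {
  wcol <- if ("w" %in% names(object)) "w" else "sw_a"
  df <- tibble::tibble(w = object[[wcol]])
  df <- df[!is.na(df$w), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$w)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = sprintf("weight (%s)", wcol), y = "participants") +
    ggplot2::theme_minimal()
}
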