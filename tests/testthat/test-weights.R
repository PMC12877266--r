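test_that("treatment weights are exactly 1 when the models coincide", {
  co <- cached_cohort()$cohort
  # no confounders: numerator and denominator are the same marginal density
  tw <- fit_treatment_weights(co, "dairy_total", character(0))
  expect_equal(tw$sw_a, rep(1, nrow(co)), tolerance = 1e-12)
})

test_that("treatment weights match the normal-density-ratio arithmetic", {
  fix <- tibble::tibble(
    participant_id = 1:6,
    a = c(120, 250, 310, 180, 400, 90),
    x = c(0, 1, 1, 0, 1, 0)
  )
  tw <- fit_treatment_weights(fix, "a", "x")
  # independent oracle: explicit OLS fit and both normal densities by hand
  fit <- lm(a ~ x, data = fix)
  mu <- fitted(fit)
  s_den <- sqrt(sum(residuals(fit)^2) / fit$df.residual)
  oracle <- dnorm(fix$a, mean(fix$a), sd(fix$a)) / dnorm(fix$a, mu, s_den)
  expect_equal(tw$sw_a, unname(oracle), tolerance = 1e-10)
})

test_that("stabilized treatment weights restore covariate balance", {
  cc <- cached_cohort("confounded_positive", n = 10000, seed = 23)
  co <- cc$cohort
  tw <- fit_treatment_weights(co, "dairy_total", default_confounders())
  expect_true(abs(mean(tw$sw_a) - 1) < 0.1)
  co$.grp <- exposure_tertiles(co$dairy_total)
  bal <- weighted_balance(co, ".grp", default_confounders(), weights = tw$sw_a)
  expect_gt(max(bal$smd_pre), 0.1)
  expect_lt(max(bal$smd_post), 0.1)
})

test_that("incomplete-covariate rows get the documented fallback weight", {
  co <- cached_cohort()$cohort
  co$age_group[1:5] <- NA
  tw <- fit_treatment_weights(co, "dairy_total", default_confounders())
  expect_equal(tw$sw_a[1:5], rep(1, 5))
  expect_true(all(tw$incomplete_a[1:5]))
  td <- fit_treatment_weights(co, "dairy_total", default_confounders(),
                              na_action = "drop")
  expect_true(all(is.na(td$sw_a[1:5])))
})

test_that("censoring weights: no dropout and null-coefficient limits", {
  co <- cached_cohort()$cohort
  full <- dplyr::mutate(co, followed = 1)
  cw <- fit_censoring_weights(full, default_censoring_covariates())
  expect_identical(cw$sw_c, rep(1, nrow(co)))

  # generator with covariate-free censoring: weights concentrate at 1
  cc <- cached_cohort("null", n = 8000, seed = 31)
  cwn <- fit_censoring_weights(cc$cohort, default_censoring_covariates())
  expect_lt(max(abs(cwn$sw_c - 1), na.rm = TRUE), 0.15)
  expect_equal(mean(cwn$sw_c, na.rm = TRUE), 1, tolerance = 0.01)
})

test_that("censoring weights match closed-form inverse probabilities", {
  # 2 binary covariates, 8-cell saturated design with known cell counts
  grid <- expand.grid(x1 = c(0, 1), x2 = c(0, 1), C = c(0, 1))
  counts <- c(10, 20, 15, 25, 40, 60, 45, 85)
  fix <- grid[rep(seq_len(8), counts), ]
  fix$participant_id <- seq_len(nrow(fix))
  fix$followed <- fix$C
  cw <- fit_censoring_weights(fix, c("x1", "x2"))
  # oracle on the interaction-free logistic fit computed independently
  gf <- glm(C ~ x1 + x2, family = binomial(), data = fix)
  p <- predict(gf, type = "response")
  oracle <- ifelse(fix$C == 1, mean(fix$C) / p, NA_real_)
  expect_equal(cw$sw_c, unname(oracle), tolerance = 1e-10)
})

test_that("truncation caps exactly the values above the percentile", {
  w <- rep(2, 50)
  expect_equal(as.numeric(truncate_weights(w)), w)

  w2 <- as.numeric(1:1000)
  tr <- truncate_weights(w2, 99.5)
  cap <- attr(tr, "cap")
  # inverse-CDF cap: the 995th order statistic; exactly 5 values are clipped
  expect_equal(cap, 995)
  expect_equal(sum(w2 > cap), 5)
  expect_equal(as.numeric(tr), pmin(w2, cap))
  # idempotence
  tr2 <- truncate_weights(as.numeric(tr), 99.5)
  expect_equal(as.numeric(tr2), as.numeric(tr))
  expect_error(truncate_weights(numeric(0)), "no weights")
  expect_error(truncate_weights(c(1, -2)), "positive")
})

test_that("combining weights multiplies, clips, and aligns ids", {
  co <- cached_cohort()$cohort
  tw <- fit_treatment_weights(co, "dairy_total", default_confounders())
  cw <- fit_censoring_weights(co, default_censoring_covariates())
  ws <- combine_weights(tw, cw)
  # manual oracle: truncate each, multiply, truncate again (type-1 caps)
  a <- pmin(tw$sw_a, quantile(tw$sw_a, 0.995, type = 1))
  b <- pmin(cw$sw_c, quantile(cw$sw_c[!is.na(cw$sw_c)], 0.995, type = 1))
  prod <- a * b
  capw <- quantile(prod[!is.na(prod)], 0.995, type = 1)
  expect_equal(ws$w, unname(pmin(prod, capw)), tolerance = 1e-12)

  # censoring weights identically 1: combined equals truncated sw_a
  cw1 <- cw
  cw1$sw_c <- 1
  ws1 <- combine_weights(tw, cw1)
  expect_equal(ws1$w, unname(a), tolerance = 1e-12)

  bad <- cw[-1, ]
  expect_error(combine_weights(tw, bad), "different ids")
})

test_that("weight computation is invariant to row order", {
  co <- cached_cohort()$cohort
  perm <- withr::with_seed(5, sample(nrow(co)))
  ws1 <- combine_weights(
    fit_treatment_weights(co, "dairy_total", default_confounders()),
    fit_censoring_weights(co, default_censoring_covariates()))
  co2 <- co[perm, ]
  ws2 <- combine_weights(
    fit_treatment_weights(co2, "dairy_total", default_confounders()),
    fit_censoring_weights(co2, default_censoring_covariates()))
  ws2 <- ws2[match(ws1$participant_id, ws2$participant_id), ]
  expect_equal(ws1$w, ws2$w, tolerance = 1e-10)
})

test_that("effective sample size is at most n, equal iff weights equal", {
  expect_equal(effective_sample_size(rep(3, 40)), 40)
  withr::with_seed(2, w <- runif(200, 0.2, 4))
  expect_lt(effective_sample_size(w), 200)
  co <- cached_cohort()$cohort
  ws <- fit_weights_for(co)
  g <- glance(ws)
  expect_lte(g$ess, g$n_weighted)
  expect_s3_class(autoplot(ws), "ggplot")
})
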