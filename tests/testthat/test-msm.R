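test_that("identity link with unit weights equals ordinary least squares", {
  dat <- make_msm_fixture(n = 20, seed = 3)
  fit <- fit_msm(dat, "y", "dairy_total", c("fish_seafood", "vegetables"),
                 link = "identity")
  # oracle: plain lm on the per-100g columns
  ols <- lm(y ~ I(dairy_total / 100) + I(fish_seafood / 100) +
              I(vegetables / 100), data = dat)
  expect_equal(unname(coef(fit$fit)), unname(coef(ols)), tolerance = 1e-10)
})

test_that("duplicating rows at half weight reproduces the fit", {
  dat <- make_msm_fixture(n = 40, seed = 5)
  fit1 <- fit_msm(dat, "y", "dairy_total", "fish_seafood", link = "identity")
  dup <- dplyr::bind_rows(dat, dat)
  fit2 <- fit_msm(dup, "y", "dairy_total", "fish_seafood",
                  weights = rep(0.5, nrow(dup)), link = "identity")
  expect_equal(coef(fit1$fit), coef(fit2$fit), tolerance = 1e-10)
})

test_that("slopes vanish when the outcome is independent of the diet", {
  withr::with_seed(8, {
    dat <- tibble::tibble(
      participant_id = 1:20000,
      dairy_total = runif(20000, 100, 600),
      fish_seafood = runif(20000, 0, 150),
      y = rbinom(20000, 1, 0.3)
    )
  })
  fit <- fit_msm(dat, "y", "dairy_total", "fish_seafood", link = "logit")
  sl <- tidy(fit)
  expect_true(all(abs(sl$estimate[sl$term != "(Intercept)"]) <
                    3 * sl$std.error[sl$term != "(Intercept)"] + 1e-8))
  expect_lt(abs(coef(fit$fit)[["dairy_total"]]), 0.1)
})

test_that("identity-link ACEs have their exact closed forms", {
  co <- cached_cohort()$cohort
  co$y <- code_cdr(co$cdr_t1)
  ws <- fit_weights_for(co)
  fit <- fit_msm(co, "y", "dairy_total", other_food_groups(), weights = ws,
                 link = "identity")
  withr::with_seed(1, a <- ace_addition(fit, n_draws = 500))
  expect_equal(a$ace, 100 / 100 * unname(coef(fit$fit)[["dairy_total"]]),
               tolerance = 1e-10)
  expect_equal(a$ace, a$slope_per_100g, tolerance = 1e-10)
  withr::with_seed(1, s <- ace_substitution(fit, "fish_seafood", n_draws = 500))
  expect_equal(
    s$ace,
    unname(coef(fit$fit)[["dairy_total"]] - coef(fit$fit)[["fish_seafood"]]),
    tolerance = 1e-10)
  # delta scales linearly under the identity link
  withr::with_seed(1, a50 <- ace_addition(fit, delta = 50, n_draws = 500))
  expect_equal(a50$ace, a$ace / 2, tolerance = 1e-10)
})

test_that("substitution is antisymmetric under swapped roles", {
  co <- cached_cohort()$cohort
  co$y <- code_cdr(co$cdr_t1)
  foods_a <- other_food_groups()
  fit_a <- fit_msm(co, "y", "dairy_total", foods_a, link = "identity")
  foods_b <- c("dairy_total", setdiff(foods_a, "fish_seafood"))
  fit_b <- fit_msm(co, "y", "fish_seafood", foods_b, link = "identity")
  withr::with_seed(2, s_ab <- ace_substitution(fit_a, "fish_seafood",
                                               n_draws = 200))
  withr::with_seed(2, s_ba <- ace_substitution(fit_b, "dairy_total",
                                               n_draws = 200))
  expect_equal(s_ab$ace, -s_ba$ace, tolerance = 1e-10)
})

test_that("a null coefficient yields a zero ACE with a symmetric interval", {
  dat <- make_msm_fixture(n = 200, seed = 7)
  fit <- fit_msm(dat, "y", "dairy_total", "fish_seafood", link = "identity")
  # force the exposure coefficient (and its draws) to zero variance
  fit$fit$coefficients["dairy_total"] <- 0
  fit$vcov_robust[] <- 0
  withr::with_seed(3, a <- ace_addition(fit, n_draws = 100))
  expect_identical(a$ace, 0)
  expect_equal(a$ci_low, 0)
  expect_equal(a$ci_high, 0)
})

test_that("logit-link ACE equals the brute-force row-wise contrast", {
  dat <- make_msm_fixture(n = 50, seed = 11)
  withr::with_seed(12, w <- runif(50, 0.5, 2))
  fit <- fit_msm(dat, "y", "dairy_total", c("fish_seafood", "vegetables"),
                 weights = w, link = "logit")
  withr::with_seed(4, a <- ace_addition(fit, n_draws = 200))
  # oracle: explicit loop over rows with hand-built linear predictors
  b <- coef(fit$fit)
  contrast <- numeric(50)
  for (i in seq_len(50)) {
    eta0 <- b[["(Intercept)"]] + b[["dairy_total"]] * dat$dairy_total[i] / 100 +
      b[["fish_seafood"]] * dat$fish_seafood[i] / 100 +
      b[["vegetables"]] * dat$vegetables[i] / 100
    eta1 <- eta0 + b[["dairy_total"]]
    contrast[i] <- plogis(eta1) - plogis(eta0)
  }
  oracle <- sum(w * contrast) / sum(w)
  expect_equal(a$ace, oracle, tolerance = 1e-12)

  withr::with_seed(4, s <- ace_substitution(fit, "fish_seafood", n_draws = 200))
  contrast_f <- numeric(50)
  for (i in seq_len(50)) {
    eta0 <- b[["(Intercept)"]] + b[["dairy_total"]] * dat$dairy_total[i] / 100 +
      b[["fish_seafood"]] * dat$fish_seafood[i] / 100 +
      b[["vegetables"]] * dat$vegetables[i] / 100
    contrast_f[i] <- plogis(eta0 + b[["fish_seafood"]]) - plogis(eta0)
  }
  oracle_s <- oracle - sum(w * contrast_f) / sum(w)
  expect_equal(s$ace, oracle_s, tolerance = 1e-12)
})

test_that("simulation CI converges to the closed-form normal interval", {
  dat <- make_msm_fixture(n = 300, seed = 19)
  fit <- fit_msm(dat, "y", "dairy_total", "fish_seafood", link = "identity")
  cvec <- setNames(c(0, 1, 0), colnames(fit$X))
  se <- sqrt(fit$vcov_robust["dairy_total", "dairy_total"])
  est <- coef(fit$fit)[["dairy_total"]]
  withr::with_seed(9, ci <- parametric_ci(fit, cvec, n_draws = 40000))
  # quantile Monte-Carlo error at 40k draws is ~0.013 SE units; allow 5x
  expect_lt(abs(ci$low - (est - qnorm(0.975) * se)), 0.07 * se)
  expect_lt(abs(ci$high - (est + qnorm(0.975) * se)), 0.07 * se)
  cid <- parametric_ci(fit, cvec, method = "delta")
  expect_equal(cid$low, est + qnorm(0.025) * se, tolerance = 1e-10)
  # delta method with a functional agrees with the linear contrast version
  fn <- function(beta) sum(cvec * beta)
  cid2 <- parametric_ci(fit, fn, method = "delta")
  expect_equal(cid2$low, cid$low, tolerance = 1e-6)
})

test_that("out-of-range identity-link predictions are counted, not hidden", {
  withr::with_seed(30, {
    dat <- tibble::tibble(
      participant_id = 1:60,
      dairy_total = runif(60, 100, 900),
      fish_seafood = runif(60, 0, 150),
      y = rbinom(60, 1, pmin(0.05 + 0.001 * runif(60, 100, 900), 1))
    )
    dat$y[dat$dairy_total > 600] <- 1
  })
  fit <- fit_msm(dat, "y", "dairy_total", "fish_seafood", link = "identity")
  expect_warning(a <- ace_addition(fit, delta = 800, ci_method = "delta"),
                 "outside \\[0, 1\\]")
  expect_gt(a$n_clamped, 0)
})

test_that("substitution food must sit in the all-component model", {
  dat <- make_msm_fixture(n = 30, seed = 2)
  fit <- fit_msm(dat, "y", "dairy_total", "fish_seafood", link = "identity")
  expect_error(ace_substitution(fit, "meat", ci_method = "delta"),
               "not a covariate")
})

test_that("tidy and glance expose the fit the broom way", {
  dat <- make_msm_fixture(n = 80, seed = 21)
  fit <- fit_msm(dat, "y", "dairy_total", "fish_seafood", link = "logit")
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_equal(nrow(td), 3)
  g <- glance(fit)
  expect_equal(g$n, 80)
  expect_equal(g$link, "logit")
})
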