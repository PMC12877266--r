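test_that("scenario truths encode the intended structure", {
  null_truth <- generate_truth("null", n = 100, seed = 1)
  expect_true(all(null_truth$outcome_model$foods == 0))

  t1 <- generate_truth("table1_like", n = 100, seed = 1)
  expect_equal(unname(t1$margins$age_group), c(0.61, 0.2205, 0.1695),
               tolerance = 1e-3)
  expect_equal(sum(t1$margins$age_group), 1, tolerance = 1e-12)

  conf <- generate_truth("confounded_positive", n = 100, seed = 1)
  expect_identical(unname(conf$outcome_model$foods["dairy_total"]), 0.02)
  expect_identical(unname(conf$outcome_model$foods["fish_seafood"]), -0.01)

  expect_error(generate_truth("no_such_scenario"), "valid scenarios")
})

test_that("identity-link outcome models that can exit [0,1] are rejected", {
  truth <- generate_truth("confounded_positive", n = 50, seed = 1)
  om <- truth$outcome_model
  om$foods["dairy_total"] <- 0.5 # 0.5 per 100 g/d over a ~1000 g support
  expect_error(
    simulation_truth(truth$margins, truth$intake_model, om,
                     truth$censoring_model, n = 50, seed = 1),
    "exit \\[0, 1\\]"
  )
})

test_that("generation is deterministic and respects invariants", {
  truth <- generate_truth("confounded_positive", n = 400, seed = 99)
  a <- generate_cohort(truth)
  b <- generate_cohort(truth)
  expect_identical(a, b)

  items <- intersect(default_food_group_map()$item, names(a))
  expect_true(all(as.matrix(a[, items]) >= 0))
  expect_true(all(a$mmse >= 0 & a$mmse <= 30))
  expect_true(all(a$followed %in% c(0, 1)))
  # follow-up outcomes are absent exactly when not followed
  expect_identical(is.na(a$cdr_t1), a$followed == 0)
  expect_identical(is.na(a$score_t1), a$followed == 0)
  # caps bound the support
  caps <- truth$intake_model$cap[match(items, truth$intake_model$item)]
  expect_true(all(sweep(as.matrix(a[, items]), 2, caps, "<=")))
})

test_that("null-scenario outcome rate matches the structural intercept", {
  truth <- generate_truth("null", n = 10000, seed = 5)
  co <- generate_cohort(truth)
  # P(Y=1) = intercept + age effects averaged over margins
  m <- truth$margins$age_group
  p_true <- truth$outcome_model$intercept +
    sum(truth$outcome_model$covars * m[c("70-74", ">74")])
  p_hat <- mean(co$cdr_t1[co$followed == 1] > 0)
  # binomial SE oracle, on the followed subsample (censoring is independent)
  se_f <- sqrt(p_true * (1 - p_true) / sum(co$followed))
  expect_lt(abs(p_hat - p_true), 3 * se_f)
})

test_that("covariate-free censoring matches the logistic intercept", {
  truth <- generate_truth("null", n = 10000, seed = 6)
  p_followed <- plogis(truth$censoring_model$intercept)
  co <- generate_cohort(truth)
  se <- sqrt(p_followed * (1 - p_followed) / truth$n)
  expect_lt(abs(mean(co$followed) - p_followed), 3 * se)
})

test_that("true_ace has the exact identity-link closed form", {
  truth <- generate_truth("confounded_positive", n = 500, seed = 2)
  co <- generate_cohort(truth)
  expect_identical(true_ace(truth, co, "dairy_total", 100), 0.02)
  expect_identical(true_ace(truth, co, "dairy_fermented", 100), 0.02)
  expect_identical(true_ace(truth, co, "fish_seafood", 100), -0.01)
  expect_identical(true_ace(truth, co, "meat", 100), 0)
  expect_identical(true_ace_substitution(truth, co), 0.03)

  null_truth <- generate_truth("null", n = 500, seed = 2)
  expect_identical(true_ace(null_truth, generate_cohort(null_truth)), 0)
})

test_that("logit-link true_ace agrees with a brute-force potential-outcome draw", {
  truth <- generate_truth("confounded_logit", n = 200000, seed = 8)
  co <- generate_cohort(truth)
  ace <- true_ace(truth, co, "dairy_total", 100)
  # Monte-Carlo oracle: draw both potential outcomes per row from the
  # structural model and difference the empirical means
  groups <- rowSums(co[, c("milk_full", "milk_skim", "yogurt_plain",
                           "yogurt_flavored", "cheese_regular", "cheese_lowfat",
                           "cream", "butter", "dessert_sugary",
                           "dessert_lowfat")])
  om <- truth$outcome_model
  eta0 <- om$intercept + om$foods[["dairy_total"]] * groups / 100 +
    om$foods[["fish_seafood"]] * co$fish_seafood / 100 +
    om$covars[["age_group=70-74"]] * (co$age_group == "70-74") +
    om$covars[["age_group=>74"]] * (co$age_group == ">74") +
    om$covars[["sex=male"]] * (co$sex == "male") +
    om$covars[["smoking=current"]] * (co$smoking == "current") +
    om$covars[["hypertension=yes"]] * (co$hypertension == "yes")
  withr::with_seed(1, {
    y1 <- rbinom(nrow(co), 1, plogis(eta0 + om$foods[["dairy_total"]]))
    y0 <- rbinom(nrow(co), 1, plogis(eta0))
  })
  mc <- mean(y1) - mean(y0)
  se <- sqrt(2 * 0.25 / nrow(co))
  expect_lt(abs(ace - mc), 3 * se)
})

test_that("null scenario leaves exposure and covariates independent", {
  # The max SMD over twelve multi-level covariates has a chi-square noise
  # floor even under exact independence, so the check is against that floor:
  # permuting the exposure destroys any dependence by construction, and the
  # null scenario's max SMD must look like the permuted one (while a
  # confounded cohort's must not).
  res <- vapply(1:30, function(s) {
    co <- add_food_groups(generate_cohort(generate_truth("null", n = 10000,
                                                         seed = 500 + s)))
    co$.grp <- exposure_tertiles(co$dairy_total)
    obs <- max(weighted_balance(co, ".grp", default_confounders())$smd_pre)
    co$.grp_perm <- withr::with_seed(9000 + s, sample(co$.grp))
    perm <- max(weighted_balance(co, ".grp_perm",
                                 default_confounders())$smd_pre)
    c(obs = obs, perm = perm)
  }, numeric(2))
  # same noise floor (ratio near 1), no systematic excess
  expect_lt(mean(res["obs", ]) / mean(res["perm", ]), 1.15)
  expect_lt(mean(res["obs", ]), 0.07)
  # and far below a genuinely confounded cohort at the same n
  conf <- add_food_groups(generate_cohort(
    generate_truth("confounded_positive", n = 10000, seed = 1)))
  conf$.grp <- exposure_tertiles(conf$dairy_total)
  conf_max <- max(weighted_balance(conf, ".grp",
                                   default_confounders())$smd_pre)
  expect_gt(conf_max, 3 * mean(res["obs", ]))
})

test_that("confounded scenarios actually confound", {
  co <- cached_cohort("confounded_positive", n = 10000, seed = 3)$cohort
  co$.grp <- exposure_tertiles(co$dairy_total)
  expect_gt(max(weighted_balance(co, ".grp", default_confounders())$smd_pre),
            0.1)
})

test_that("cohort and truth round-trip to disk deterministically", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  pipeline_simulate("null", n = 50, seed = 4, out_dir = dir1)
  pipeline_simulate("null", n = 50, seed = 4, out_dir = dir2)
  for (f in c("cohort.csv", "truth.json", "cohort_dictionary.json")) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
})
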