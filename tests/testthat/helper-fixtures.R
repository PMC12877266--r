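# Shared fixtures, built in code.

other_food_groups <- function() {
  c("vegetables", "fruits", "fish_seafood", "meat", "eggs", "grains",
    "alcohol", "sugary_processed", "high_fat")
}

# Deterministic wide item-intake table for aggregation tests.
make_item_table <- function(n = 8, seed = 42) {
  map <- default_food_group_map()
  withr::with_seed(seed, {
    out <- tibble::tibble(participant_id = seq_len(n))
    for (it in map$item) out[[it]] <- round(runif(n, 0, 300), 1)
    out
  })
}

# Minimal hand-built cohort for eligibility tests.
make_eligibility_cohort <- function() {
  tibble::tibble(
    participant_id = 1:8,
    age = c(55, 70, 70, 70, 70, 60, 70, 70),
    sex = c("female", "female", "female", "male", "female", "female",
            "female", "female"),
    mmse = c(28, 23, 28, 28, 28, 24, 28, 28),
    energy_kcal = c(2000, 2000, 450, 700, 2000, 2000, 2000, 2000),
    followed = c(1, 1, 1, 1, 0, 1, 1, 1),
    followup_years = c(5, 5, 5, 5, NA, 5, 2.5, 2.5),
    time2_years = c(NA, NA, NA, NA, NA, NA, 9, NA)
  )
}

# Small analysis table with known linear structure for MSM tests.
make_msm_fixture <- function(n = 50, seed = 11, binary_noise = TRUE) {
  withr::with_seed(seed, {
    dat <- tibble::tibble(
      participant_id = seq_len(n),
      dairy_total = runif(n, 100, 600),
      fish_seafood = runif(n, 0, 150),
      vegetables = runif(n, 50, 400)
    )
    eta <- -1.5 + 0.2 * dat$dairy_total / 100 - 0.1 * dat$fish_seafood / 100
    dat$y <- rbinom(n, 1, plogis(eta))
    dat
  })
}

# One standard generated cohort reused across tests (small, fast).
cached_cohort <- local({
  cache <- new.env()
  function(scenario = "confounded_positive", n = 3000, seed = 7) {
    key <- paste(scenario, n, seed, sep = "_")
    if (is.null(cache[[key]])) {
      truth <- generate_truth(scenario, n = n, seed = seed)
      cache[[key]] <- list(truth = truth,
                           cohort = add_food_groups(generate_cohort(truth)))
    }
    cache[[key]]
  }
})

fit_weights_for <- function(cohort, exposure = "dairy_total") {
  tw <- fit_treatment_weights(cohort, exposure, default_confounders())
  cw <- fit_censoring_weights(cohort, default_censoring_covariates())
  combine_weights(tw, cw)
}
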