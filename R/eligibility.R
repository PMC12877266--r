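#' Eligibility criteria
#'
#' Bounds follow the study design: participants must be over `min_age` years
#' (exclusive), cognitively healthy (`mmse > min_mmse`, exclusive), with total
#' energy strictly inside sex-specific bounds (females 500-3500 kcal/d, males
#' 800-4000 kcal/d, both exclusive), and re-assessed at least
#' `min_followup_years` after baseline (inclusive).
#'
#' @param min_age exclusive minimum age in years.
#' @param min_mmse exclusive minimum MMSE.
#' @param kcal_female,kcal_male exclusive (low, high) kcal/d bounds.
#' @param min_followup_years inclusive minimum follow-up interval.
#' @return an `eligibility_criteria` list.
#' @export
eligibility_criteria <- function(min_age = 59, min_mmse = 23,
                                 kcal_female = c(500, 3500),
                                 kcal_male = c(800, 4000),
                                 min_followup_years = 3) {
  for (b in list(kcal_female, kcal_male)) {
    if (length(b) != 2 || b[1] >= b[2]) {
      abort_validation("kcal bounds must be (low, high) with low < high")
    }
  }
  structure(
    list(min_age = min_age, min_mmse = min_mmse, kcal_female = kcal_female,
         kcal_male = kcal_male, min_followup_years = min_followup_years),
    class = "eligibility_criteria"
  )
}

#' Apply eligibility and follow-up rules
#'
#' Excludes participants failing the baseline rules, in a fixed precedence
#' order so the exclusion log is reproducible: age, then MMSE, then kcal. Each
#' excluded row gets exactly one reason code (the first failing rule).
#' Participants passing the baseline rules form the *eligible-for-weighting*
#' set and are all returned; among them, those with a follow-up assessment at
#' least `min_followup_years` after baseline form the *analysis set*
#' (`in_analysis_set`). If the Time-1 assessment is absent or too short but a
#' Time-2 assessment (`time2_years`, with outcomes) is available and long
#' enough, Time 2 is used as the follow-up (`followup_used == "time2"`).
#' Participants without any qualifying follow-up stay in the eligible table
#' (they still inform the weight models) and are logged with reason
#' `"no_followup"`.
#'
#' The operation is idempotent: re-applying it to its own eligible output
#' yields the same table.
#'
#' @param cohort cohort tibble with columns `participant_id`, `age`, `sex`,
#'   `mmse`, `energy_kcal`, `followed`, `followup_years`, and optionally
#'   `time2_years` (plus time-2 outcome columns).
#' @param criteria an [eligibility_criteria()] object.
#' @return list with `eligible` (the weighting set, plus `in_analysis_set`,
#'   `followup_used`, `followup_years_used`) and `exclusions` (tibble
#'   `participant_id`, `reason`).
#' @export
apply_eligibility <- function(cohort, criteria = eligibility_criteria()) {
  assert_cols(cohort, c("participant_id", "age", "sex", "mmse", "energy_kcal",
                        "followed", "followup_years"), "cohort")
  kc_lo <- ifelse(cohort$sex == "female",
                  criteria$kcal_female[1], criteria$kcal_male[1])
  kc_hi <- ifelse(cohort$sex == "female",
                  criteria$kcal_female[2], criteria$kcal_male[2])
  reason <- rep(NA_character_, nrow(cohort))
  reason[is.na(reason) & !(cohort$age > criteria$min_age)] <- "age"
  reason[is.na(reason) & !(cohort$mmse > criteria$min_mmse)] <- "mmse"
  reason[is.na(reason) &
           !(cohort$energy_kcal > kc_lo & cohort$energy_kcal < kc_hi)] <- "kcal"

  eligible <- cohort[is.na(reason), , drop = FALSE]

  t1_ok <- eligible$followed == 1 & !is.na(eligible$followup_years) &
    eligible$followup_years >= criteria$min_followup_years
  has_t2 <- if ("time2_years" %in% names(eligible)) {
    !is.na(eligible$time2_years) &
      eligible$time2_years >= criteria$min_followup_years
  } else rep(FALSE, nrow(eligible))
  use_t2 <- !t1_ok & has_t2

  eligible$in_analysis_set <- t1_ok | use_t2
  eligible$followup_used <- dplyr::case_when(
    t1_ok ~ "time1", use_t2 ~ "time2", TRUE ~ NA_character_)
  t2_years <- if ("time2_years" %in% names(eligible)) eligible$time2_years
              else rep(NA_real_, nrow(eligible))
  eligible$followup_years_used <- dplyr::case_when(
    t1_ok ~ eligible$followup_years,
    use_t2 ~ t2_years,
    TRUE ~ NA_real_)

  exclusions <- dplyr::bind_rows(
    tibble::tibble(participant_id = cohort$participant_id[!is.na(reason)],
                   reason = reason[!is.na(reason)]),
    tibble::tibble(
      participant_id = eligible$participant_id[!eligible$in_analysis_set],
      reason = "no_followup")
  )
  list(eligible = tibble::as_tibble(eligible), exclusions = exclusions)
}

#' Cumulative-average exposure over two FFQ waves
#'
#' Element-wise mean of the two waves' food intakes, for the sensitivity path
#' that smooths diet over a longer horizon. Participants absent from (or with
#' missing values in) the second wave are excluded from the result and
#' reported.
#'
#' @param wave0,wave1 tibbles with the id column plus identical intake columns
#'   (g/d).
#' @param id id column name.
#' @return tibble of averaged intakes for participants present and complete in
#'   both waves, with attribute `"excluded_ids"` listing the dropped ids.
#' @export
cumulative_average_exposure <- function(wave0, wave1, id = "participant_id") {
  assert_cols(wave0, id, "wave-0 table")
  assert_cols(wave1, id, "wave-1 table")
  cols <- setdiff(names(wave0), id)
  assert_cols(wave1, cols, "wave-1 table")
  w1 <- wave1[match(wave0[[id]], wave1[[id]]), , drop = FALSE]
  m0 <- as.matrix(wave0[, cols, drop = FALSE])
  m1 <- as.matrix(w1[, cols, drop = FALSE])
  complete <- stats::complete.cases(m1) & stats::complete.cases(m0)
  excluded <- wave0[[id]][!complete]
  if (length(excluded) > 0) {
    rlang::inform(sprintf(
      "%d participant(s) missing a wave-1 FFQ excluded from the cumulative-average path",
      length(excluded)))
  }
  avg <- (m0[complete, , drop = FALSE] + m1[complete, , drop = FALSE]) / 2
  out <- dplyr::bind_cols(
    tibble::tibble(!!id := wave0[[id]][complete]),
    tibble::as_tibble(avg)
  )
  attr(out, "excluded_ids") <- excluded
  out
}

#' Cumulative-average sensitivity cohort from a two-wave table
#'
#' For cohorts carrying a second FFQ wave (columns suffixed `_w2`, as produced
#' by [generate_cohort()] with `waves = 2`), replaces each item intake by the
#' cumulative average of the two waves via [cumulative_average_exposure()].
#' The longer-horizon outcome columns (`cdr_t2`, `score_t2`, `time2_years`)
#' are untouched, so the grid can be re-run against the later follow-up.
#'
#' @param cohort two-wave cohort tibble.
#' @param id id column name.
#' @return the cohort with averaged item intakes and the `_w2` columns
#'   removed; participants incomplete in wave 2 are dropped (and reported).
#' @export
cumulative_average_cohort <- function(cohort, id = "participant_id") {
  w2_cols <- grep("_w2$", names(cohort), value = TRUE)
  if (length(w2_cols) == 0) {
    abort_validation("cohort has no second-wave (_w2) intake columns")
  }
  items <- sub("_w2$", "", w2_cols)
  assert_cols(cohort, items, "two-wave cohort")
  wave0 <- cohort[, c(id, items)]
  wave1 <- cohort[, c(id, w2_cols)]
  names(wave1) <- c(id, items)
  avg <- cumulative_average_exposure(wave0, wave1, id = id)
  out <- cohort[cohort[[id]] %in% avg[[id]],
                setdiff(names(cohort), c(items, w2_cols))]
  out <- dplyr::left_join(out, avg, by = id)
  attr(out, "excluded_ids") <- attr(avg, "excluded_ids")
  out
}
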