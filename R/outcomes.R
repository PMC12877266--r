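#' Code clinical dementia rating as binary impairment
#'
#' Any rating above 0 (0.5 = mild cognitive impairment, 1+ = dementia) is coded
#' impaired; 0 is healthy. `NA` (e.g. not followed up) propagates.
#'
#' @param score numeric CDR values (0, 0.5, 1, ...).
#' @return integer vector of 0/1 (NA preserved).
#' @export
code_cdr <- function(score) {
  bad <- !is.na(score) & (score < 0)
  if (any(bad)) {
    abort_validation(sprintf("negative CDR value(s): %s",
                             paste(unique(score[bad]), collapse = ", ")))
  }
  as.integer(score > 0)
}

#' Code subjective cognitive decline caseness from questionnaire items
#'
#' A participant is a case when they answer yes to 3 or more items, or to item
#' 5, or — depending on `rule` — to any of (default) or all of the special
#' items A, 4, 5, 7, 8. The wording of the special-item clause is ambiguous in
#' the instrument description, so both readings are available. Participants
#' with a missing response among the items needed by the rule are returned as
#' `NA` (flagged missing), never silently coded 0.
#'
#' @param responses data frame of 0/1 (or logical) item responses; columns
#'   named `item_1` ... `item_9`, `item_A` (the configured `items`).
#' @param items item columns counted for the ">= 3 yes" clause.
#' @param special_items items in the A/4/5/7/8 clause.
#' @param rule `"any_of"` (default) or `"all_of"` for the special-item clause.
#' @return integer vector of 0/1 with `NA` for incomplete responders.
#' @export
code_scd <- function(responses,
                     items = paste0("item_", c(1:9, "A")),
                     special_items = paste0("item_", c("A", 4, 5, 7, 8)),
                     rule = c("any_of", "all_of")) {
  rule <- match.arg(rule)
  assert_cols(responses, union(items, special_items), "SCD responses")
  mat <- sapply(responses[, union(items, special_items), drop = FALSE],
                function(x) as.integer(as.logical(x)))
  mat <- matrix(mat, nrow = nrow(responses),
                dimnames = list(NULL, union(items, special_items)))
  count_yes <- rowSums(mat[, items, drop = FALSE])
  item5 <- mat[, "item_5"]
  special <- if (rule == "any_of") {
    as.integer(rowSums(mat[, special_items, drop = FALSE]) >= 1)
  } else {
    as.integer(rowSums(mat[, special_items, drop = FALSE]) ==
                 length(special_items))
  }
  out <- as.integer(count_yes >= 3 | item5 == 1 | special == 1)
  out[!stats::complete.cases(mat)] <- NA_integer_
  out
}

#' Dichotomize continuous cognitive scores
#'
#' Impairment is scored *strictly below* the threshold ("lower than" — a score
#' equal to the threshold is not impaired). Two modes:
#' * fixed cutoff (`threshold` given), reproducing the instrument cutpoints
#'   (verbal 36, memory 48, DO40 40, Stroop 24, CERAD 11);
#' * percentile (default 75th), used when test scores pile up near the maximum
#'   and leave too little variability for a continuous analysis. The percentile
#'   uses the type-7 linear-interpolation quantile; with weights, the smallest
#'   score whose normalized cumulative weight reaches the target (documented
#'   weighted convention).
#'
#' @param scores numeric scores (`NA` allowed; propagates).
#' @param threshold fixed cutoff; if `NULL`, the percentile rule applies.
#' @param percentile percentile (0-100) for the percentile rule.
#' @param weights optional positive weights for the percentile computation.
#' @return list: `impaired` (0/1 integer, `NA` preserved), `threshold` (the
#'   realized threshold, for the audit log) and `rule`.
#' @export
dichotomize <- function(scores, threshold = NULL, percentile = 75,
                        weights = NULL) {
  obs <- scores[!is.na(scores)]
  if (is.null(threshold)) {
    if (length(unique(obs)) < 2) {
      abort_validation(
        "percentile dichotomization needs >= 2 distinct non-missing scores")
    }
    if (is.null(weights)) {
      threshold <- quantile7(obs, percentile / 100)
    } else {
      w <- weights[!is.na(scores)]
      ord <- order(obs)
      cw <- cumsum(w[ord]) / sum(w)
      threshold <- obs[ord][which(cw >= percentile / 100)[1]]
    }
    rule <- sprintf("p%g", percentile)
  } else {
    rule <- sprintf("cutoff%g", threshold)
  }
  list(impaired = as.integer(scores < threshold),
       threshold = unname(threshold), rule = rule)
}

#' Default outcome specifications
#'
#' One row per cognitive outcome: how the binary impairment indicator is
#' derived. CDR and SCD have their own coding rules; the continuous tests are
#' dichotomized either at the instrument cutpoints (`cutoff`) or at the 75th
#' percentile (`percentile`, the default mode because scores cluster near the
#' instrument maxima).
#'
#' @param mode `"percentile"` (default) or `"cutoff"` for the continuous tests.
#' @return tibble: `outcome`, `kind`, `rule`, `cutoff`, `percentile`.
#' @export
default_outcome_specs <- function(mode = c("percentile", "cutoff")) {
  mode <- match.arg(mode)
  tibble::tribble(
    ~outcome,          ~kind,            ~cutoff,
    "cdr",             "scale",          NA_real_,
    "scd",             "questionnaire",  NA_real_,
    "verbal_fluency",  "continuous",     36,
    "memory",          "continuous",     48,
    "do40",            "continuous",     40,
    "stroop",          "continuous",     24,
    "cerad",           "continuous",     11
  ) %>%
    dplyr::mutate(
      rule = dplyr::case_when(
        .data$kind == "scale" ~ "cdr",
        .data$kind == "questionnaire" ~ "scd",
        mode == "cutoff" ~ "cutoff",
        TRUE ~ "percentile"
      ),
      percentile = ifelse(.data$kind == "continuous", 75, NA_real_)
    )
}
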