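# Internal helpers shared across modules.

# Hard error (exit code 2 territory in the CLI) for malformed inputs/config.
abort_validation <- function(msg) {
  rlang::abort(msg, class = "dietmsm_validation_error")
}

# Error in a model-fitting stage (exit code 3 in the CLI).
abort_estimation <- function(msg) {
  rlang::abort(msg, class = "dietmsm_estimation_error")
}

assert_cols <- function(data, cols, what = "input") {
  miss <- setdiff(cols, names(data))
  if (length(miss) > 0) {
    abort_validation(sprintf(
      "%s is missing required column%s: %s",
      what, if (length(miss) > 1) "s" else "", paste(miss, collapse = ", ")
    ))
  }
  invisible(data)
}

# All quantiles in the package use the type-7 (linear interpolation) convention.
quantile7 <- function(x, p) {
  stats::quantile(x, probs = p, type = 7, names = FALSE, na.rm = FALSE)
}

# Weighted moments under the frequency-weight convention: weights act as
# (normalized) replication counts, so the variance denominator is sum(w).
wtd_mean <- function(x, w) sum(w * x) / sum(w)

wtd_var <- function(x, w) {
  m <- wtd_mean(x, w)
  sum(w * (x - m)^2) / sum(w)
}

# Effective sample size implied by a weight vector: (sum w)^2 / sum(w^2).
#' Effective sample size of a weight vector
#'
#' @param w positive weights (NAs dropped).
#' @return `(sum(w))^2 / sum(w^2)`, at most `length(w)` with equality iff all
#'   weights are equal.
#' @export
effective_sample_size <- function(w) {
  w <- w[!is.na(w)]
  if (length(w) == 0) return(0)
  sum(w)^2 / sum(w^2)
}
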