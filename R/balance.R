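#' Standardized mean difference for a binary variable
#'
#' Pooled form `|p1 - p2| / sqrt((p1(1-p1) + p2(1-p2)) / 2)`. When both groups
#' are degenerate (variance 0) the SMD is 0 if the proportions agree and `Inf`
#' (flagged by a warning) if they do not.
#'
#' @param p1,p2 group proportions in \[0, 1\].
#' @return nonnegative SMD (vectorized).
#' @export
smd_binary <- function(p1, p2) {
  if (any(c(p1, p2) < 0 | c(p1, p2) > 1)) {
    abort_validation("proportions must lie in [0, 1]")
  }
  v <- (p1 * (1 - p1) + p2 * (1 - p2)) / 2
  out <- abs(p1 - p2) / sqrt(v)
  degenerate <- v == 0
  out[degenerate & p1 == p2] <- 0
  if (any(degenerate & p1 != p2)) {
    rlang::warn("degenerate groups with unequal proportions: SMD is infinite")
    out[degenerate & p1 != p2] <- Inf
  }
  out
}

#' Multivariate standardized mean difference for a categorical variable
#'
#' Mahalanobis-type construction: with level proportions `p1`, `p2` over K
#' levels, take the difference `d` of the first K-1 proportions and
#' `sqrt(d' S^-1 d)` where `S` averages the two multinomial covariance matrices
#' `diag(p) - p p'` (first K-1 levels). For K = 2 this reduces exactly to the
#' pooled binary form. If `S` is singular, zero-variance levels are dropped
#' with a warning.
#'
#' @param p1,p2 level-proportion vectors (same length, each summing to 1).
#' @return nonnegative SMD.
#' @export
smd_categorical <- function(p1, p2) {
  if (length(p1) != length(p2) || length(p1) < 2) {
    abort_validation("need proportion vectors of equal length >= 2")
  }
  if (abs(sum(p1) - 1) > 1e-8 || abs(sum(p2) - 1) > 1e-8) {
    abort_validation("proportions must each sum to 1")
  }
  K <- length(p1)
  keep <- seq_len(K - 1)
  covm <- function(p) {
    q <- p[keep]
    diag(q, nrow = length(q)) - outer(q, q)
  }
  d <- (p1 - p2)[keep]
  S <- (covm(p1) + covm(p2)) / 2
  inv <- tryCatch(solve(S), error = function(e) NULL)
  if (is.null(inv)) {
    rlang::warn("singular covariance in categorical SMD; dropping dependent levels")
    nz <- diag(S) > 1e-12
    if (!any(nz)) return(0)
    d <- d[nz]
    inv <- MASS::ginv(S[nz, nz, drop = FALSE])
  }
  sqrt(max(0, drop(t(d) %*% inv %*% d)))
}

#' Standardized mean difference for a continuous variable
#'
#' `|m1 - m2| / sqrt((s1^2 + s2^2) / 2)` with the groups' own variances.
#'
#' @param m1,m2 group means.
#' @param s1,s2 group standard deviations.
#' @return nonnegative SMD.
#' @export
smd_continuous <- function(m1, s1, m2, s2) {
  abs(m1 - m2) / sqrt((s1^2 + s2^2) / 2)
}

#' Multigroup SMD from a levels-by-groups count table
#'
#' One SMD per variable across three (or more) exposure groups: the arithmetic
#' mean of the SMD over all unordered group pairs. Group denominators are the
#' sums of the (non-missing) category counts supplied. Two-level variables use
#' the pooled binary form on the first level's proportion; variables with three
#' or more levels use the Mahalanobis-type categorical form.
#'
#' @param counts numeric matrix or data frame, rows = category levels, columns
#'   = groups.
#' @return the averaged pairwise SMD.
#' @examples
#' # sex (female/male) across three dairy-consumption groups
#' multigroup_smd(cbind(g1 = c(91, 54), g2 = c(428, 360), g3 = c(487, 326)))
#' @export
multigroup_smd <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) abort_validation("need at least 2 groups")
  nk <- colSums(counts)
  if (any(nk == 0)) abort_validation("every group needs a positive total count")
  props <- sweep(counts, 2, nk, "/")
  pairs <- utils::combn(ncol(counts), 2)
  vals <- apply(pairs, 2, function(ij) {
    if (nrow(props) == 2) {
      smd_binary(props[1, ij[1]], props[1, ij[2]])
    } else {
      smd_categorical(props[, ij[1]], props[, ij[2]])
    }
  })
  mean(vals)
}

#' Example baseline characteristics counts
#'
#' Covariate category counts from a population-based cohort of older adults,
#' stratified into three dairy-consumption groups (once or less, more than once
#' but less than three times, three or more times per day). Used in examples
#' and tests of the multigroup SMD routines.
#'
#' @return tibble: `variable`, `level`, and one count column per consumption
#'   group.
#' @export
example_baseline_counts <- function() {
  readr::read_csv(
    system.file("extdata", "baseline_counts.csv", package = "dietmsm"),
    show_col_types = FALSE
  )
}

#' Multigroup SMDs for every variable of a stacked count table
#'
#' @param counts a tibble like [example_baseline_counts()]: `variable`,
#'   `level`, then one count column per group.
#' @return tibble: `variable`, `smd`.
#' @export
baseline_smd_table <- function(counts) {
  groups <- setdiff(names(counts), c("variable", "level"))
  counts %>%
    dplyr::group_by(.data$variable) %>%
    dplyr::summarise(
      smd = multigroup_smd(as.matrix(dplyr::pick(dplyr::all_of(groups)))),
      .groups = "drop"
    )
}

#' Tertile grouping of a continuous exposure
#'
#' Rank-based thirds (deterministic tie handling), for Table-1-style
#' stratification and balance checks across exposure levels.
#'
#' @param x continuous exposure values.
#' @param n number of groups (default 3).
#' @return factor with levels `T1 < ... < Tn`.
#' @export
exposure_tertiles <- function(x, n = 3) {
  factor(paste0("T", dplyr::ntile(x, n)), levels = paste0("T", seq_len(n)))
}

# SMD for one covariate across the levels of `g`, with weights.
smd_one <- function(x, g, w) {
  lev <- levels(g)
  if (is.numeric(x) && !is.factor(x)) {
    ms <- purrr::map(lev, function(l) {
      xi <- x[g == l]; wi <- w[g == l]
      c(m = wtd_mean(xi, wi), s = sqrt(wtd_var(xi, wi)))
    })
    pairs <- utils::combn(length(lev), 2)
    vals <- apply(pairs, 2, function(ij) {
      a <- ms[[ij[1]]]; b <- ms[[ij[2]]]
      smd_continuous(a["m"], a["s"], b["m"], b["s"])
    })
    return(mean(vals))
  }
  x <- factor(x)
  counts <- sapply(lev, function(l) {
    sapply(levels(x), function(v) sum(w[g == l & x == v]))
  })
  multigroup_smd(counts)
}

#' Covariate balance report before and after weighting
#'
#' Computes, for every configured confounder, the standardized mean difference
#' across the levels of a categorical exposure grouping — unweighted
#' (`smd_pre`) and, if weights are supplied, weighted (`smd_post`). Weighted
#' proportions, means and variances replace the raw ones in the same SMD
#' formulas, under the frequency-weight convention. A covariate is flagged
#' balanced when its post-weighting SMD is below the threshold (0.1 by
#' convention).
#'
#' @param data cohort tibble (rows = participants to be graded).
#' @param group name of the categorical grouping column (e.g. exposure
#'   tertiles from [exposure_tertiles()]).
#' @param confounders character vector of covariate column names.
#' @param weights `NULL` (unweighted report only), a numeric vector, the name
#'   of a weight column in `data`, or a weight set from [combine_weights()]
#'   (its `w` joined by `participant_id`).
#' @param threshold balance threshold (default 0.1).
#' @return a `balance_report` tibble: `covariate`, `kind`, `smd_pre`,
#'   `smd_post`, `balanced`.
#' @export
weighted_balance <- function(data, group, confounders, weights = NULL,
                             threshold = 0.1) {
  assert_cols(data, c(group, confounders), "balance input")
  g <- factor(data[[group]])
  w <- resolve_weights(data, weights)
  if (!is.null(w)) {
    # rows without a weight (e.g. censored participants) are not graded in the
    # weighted report; they still enter the unweighted one
    graded <- !is.na(w)
    if (any(!is.finite(w[graded]) | w[graded] <= 0)) {
      abort_validation("weights must be positive and finite for all graded rows")
    }
    if (any(tapply(w[graded], g[graded], sum) <= 0, na.rm = TRUE)) {
      abort_validation("a grouping level has total weight 0")
    }
  }
  unit <- rep(1, nrow(data))
  rows <- purrr::map_dfr(confounders, function(v) {
    x <- data[[v]]
    kind <- if (is.numeric(x) && !is.factor(x)) "continuous"
      else if (length(unique(stats::na.omit(as.character(x)))) <= 2) "binary"
      else "categorical"
    ok <- !is.na(x)
    okw <- ok & !is.na(w %||% unit)
    tibble::tibble(
      covariate = v, kind = kind,
      smd_pre = smd_one(x[ok], droplevels(g[ok]), unit[ok]),
      smd_post = if (is.null(w)) NA_real_
                 else smd_one(x[okw], droplevels(g[okw]), w[okw])
    )
  })
  rows$balanced <- ifelse(is.na(rows$smd_post), rows$smd_pre < threshold,
                          rows$smd_post < threshold)
  out <- structure(rows, threshold = threshold, group = group,
                   class = c("balance_report", class(rows)))
  out
}

resolve_weights <- function(data, weights) {
  if (is.null(weights)) return(NULL)
  if (inherits(weights, "weight_set") || is.data.frame(weights)) {
    wcol <- if ("w" %in% names(weights)) "w" else "sw_a"
    j <- weights[match(data$participant_id, weights$participant_id), ]
    return(j[[wcol]])
  }
  if (is.character(weights) && length(weights) == 1) {
    assert_cols(data, weights, "balance input")
    return(data[[weights]])
  }
  if (length(weights) != nrow(data)) {
    abort_validation("weights must have one value per row")
  }
  weights
}

#' Love plot of a balance report
#'
#' @param object a `balance_report`.
#' @param ... unused.
#' @return a ggplot: one point per covariate before/after weighting, with the
#'   balance threshold as a dashed line.
#' @export
autoplot.balance_report <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            c("smd_pre", "smd_post"),
                            names_to = "stage", values_to = "smd")
  df$stage <- factor(df$stage, c("smd_pre", "smd_post"),
                     c("unweighted", "weighted"))
  df <- df[!is.na(df$smd), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$smd, y = .data$covariate,
                                   colour = .data$stage)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = attr(object, "threshold"),
                        linetype = "dashed") +
    ggplot2::labs(x = "standardized mean difference", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}
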