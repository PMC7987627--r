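# Paired prone/supine gain assessment.
#
# Three complementary views of "did switching setup help": an aggregate
# paired t-test on the penalty scores, a per-patient gain count with an
# exact binomial (Clopper-Pearson) confidence interval, and the data behind
# a bullet-arrow chart (supine penalty as bullet, prone as arrowhead).

#' Pair prone and supine penalty scores per patient
#'
#' @param scores Penalty table as returned by [score_cohort()] (columns
#'   `patient_id`, `setup`, `score`), or any long table with those columns.
#'
#' @return A tibble `patient_id, supine, prone, delta` where
#'   `delta = prone - supine`; a dosimetric gain for prone is `delta < 0`.
#' @export
pair_scores <- function(scores) {
  required <- c("patient_id", "setup", "score")
  if (!all(required %in% names(scores))) {
    rlang::abort("`scores` needs columns patient_id, setup, score.",
                 class = "dosegain_error_invalid_argument")
  }
  out <- scores |>
    dplyr::select(dplyr::all_of(required)) |>
    tidyr::pivot_wider(names_from = "setup", values_from = "score") |>
    dplyr::filter(!is.na(.data$supine), !is.na(.data$prone)) |>
    dplyr::mutate(delta = .data$prone - .data$supine) |>
    dplyr::arrange(.data$patient_id)
  out
}

#' Paired t-test on penalty scores
#'
#' Classical paired t-test on the per-patient differences prone - supine.
#'
#' @param supine,prone Numeric vectors of equal length (paired by position).
#'
#' @return A tibble `t, df, p_value, mean_delta`.
#' @export
paired_t <- function(supine, prone) {
  if (length(supine) != length(prone) || length(supine) < 2) {
    rlang::abort("Need two equal-length score vectors with n >= 2.",
                 class = "dosegain_error_invalid_argument")
  }
  delta <- prone - supine
  if (stats::sd(delta) == 0) {
    rlang::abort("All paired differences are identical; t-test is degenerate.",
                 class = "dosegain_error_degenerate_test")
  }
  tt <- stats::t.test(prone, supine, paired = TRUE)
  tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, mean_delta = mean(delta))
}

#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' Interval from Beta-distribution quantiles: lower bound
#' `qbeta(a/2, k, n-k+1)`, upper `qbeta(1-a/2, k+1, n-k)`, with the lower
#' bound 0 when k = 0 and the upper 1 when k = n.
#'
#' @param successes Number of successes k, `0 <= k <= n`.
#' @param n Number of trials, `n >= 1`.
#' @param level Confidence level, default 0.95.
#'
#' @return A tibble `proportion, ci_low, ci_high`.
#' @export
#'
#' @examples
#' exact_binomial_ci(72, 116)
exact_binomial_ci <- function(successes, n, level = 0.95) {
  if (length(successes) != 1 || length(n) != 1 || n < 1 ||
      successes < 0 || successes > n ||
      successes != round(successes) || n != round(n)) {
    rlang::abort("Need integer counts with 0 <= successes <= n, n >= 1.",
                 class = "dosegain_error_invalid_argument")
  }
  if (level <= 0 || level >= 1) {
    rlang::abort("`level` must be in (0, 1).",
                 class = "dosegain_error_invalid_argument")
  }
  a <- 1 - level
  low <- if (successes == 0) 0 else stats::qbeta(a / 2, successes, n - successes + 1)
  high <- if (successes == n) 1 else stats::qbeta(1 - a / 2, successes + 1, n - successes)
  tibble::tibble(proportion = successes / n, ci_low = low, ci_high = high)
}

#' Count dosimetric gains in a paired cohort
#'
#' A gain is a strict reduction of the penalty score when switching from
#' supine to prone (`delta < 0`); ties are conservatively counted as no
#' gain. Attaches the exact binomial confidence interval of the gain
#' proportion and the aggregate paired t-test.
#'
#' @param pairs Paired-score table from [pair_scores()].
#' @param subset Optional logical vector (or one-argument predicate applied
#'   to `pairs`) selecting a subgroup.
#' @param level Confidence level for the gain-proportion interval.
#'
#' @return A one-row tibble: `n`, `n_gain`, `proportion`, `ci_low`,
#'   `ci_high`, `mean_supine`, `mean_prone`, `t`, `t_p_value`,
#'   `median_supine`, `median_prone`, `median_delta`, plus min/max per setup.
#' @export
count_gains <- function(pairs, subset = NULL, level = 0.95) {
  if (!is.null(subset)) {
    keep <- if (is.function(subset)) subset(pairs) else subset
    pairs <- pairs[keep, , drop = FALSE]
  }
  if (nrow(pairs) == 0) {
    rlang::abort("Empty subgroup: no paired scores to assess.",
                 class = "dosegain_error_empty_subgroup")
  }
  n <- nrow(pairs)
  n_gain <- sum(pairs$delta < 0)
  ci <- exact_binomial_ci(n_gain, n, level)
  tt <- if (n >= 2 && stats::sd(pairs$delta) > 0) {
    paired_t(pairs$supine, pairs$prone)
  } else {
    tibble::tibble(t = NA_real_, df = NA_real_, p_value = NA_real_,
                   mean_delta = mean(pairs$delta))
  }
  tibble::tibble(
    n = n, n_gain = n_gain,
    proportion = ci$proportion, ci_low = ci$ci_low, ci_high = ci$ci_high,
    mean_supine = mean(pairs$supine), mean_prone = mean(pairs$prone),
    t = tt$t, t_p_value = tt$p_value,
    median_supine = stats::median(pairs$supine),
    median_prone = stats::median(pairs$prone),
    median_delta = stats::median(pairs$delta),
    min_supine = min(pairs$supine), max_supine = max(pairs$supine),
    min_prone = min(pairs$prone), max_prone = max(pairs$prone),
    min_delta = min(pairs$delta), max_delta = max(pairs$delta)
  )
}

#' Gain rates above and below a baseline-penalty threshold
#'
#' Splits the cohort at a supine-penalty threshold, summarises the gain in
#' each subgroup, and tests whether the gain rate differs between them.
#'
#' @param pairs Paired-score table from [pair_scores()].
#' @param split_at Supine penalty threshold (subgroups `supine < split_at`
#'   and `supine >= split_at`).
#' @param level Confidence level.
#' @param method Two-proportion test: Fisher's exact test (default) or the
#'   chi-square test.
#'
#' @return A list with `subgroups` (two-row tibble of [count_gains()]
#'   summaries labelled by subgroup) and `p_value` of the between-subgroup
#'   comparison.
#' @export
split_gains <- function(pairs, split_at = 2, level = 0.95,
                        method = c("fisher", "chisq")) {
  below <- pairs$supine < split_at
  groups <- dplyr::bind_rows(
    dplyr::mutate(count_gains(pairs, below, level),
                  subgroup = sprintf("supine < %g", split_at), .before = 1),
    dplyr::mutate(count_gains(pairs, !below, level),
                  subgroup = sprintf("supine >= %g", split_at), .before = 1)
  )
  p <- two_proportion_test(groups$n_gain[1], groups$n[1],
                           groups$n_gain[2], groups$n[2], method = method)
  list(subgroups = groups, p_value = p)
}

#' Two-sided comparison of two binomial proportions
#'
#' @param k1,n1 Successes and trials in group 1.
#' @param k2,n2 Successes and trials in group 2.
#' @param method `"fisher"` (exact test on the 2x2 table, default) or
#'   `"chisq"` (continuity-corrected chi-square).
#'
#' @return Two-sided p-value.
#' @export
two_proportion_test <- function(k1, n1, k2, n2, method = c("fisher", "chisq")) {
  method <- match.arg(method)
  if (n1 < 1 || n2 < 1 || k1 < 0 || k2 < 0 || k1 > n1 || k2 > n2) {
    rlang::abort("Need 0 <= k <= n with n >= 1 in both groups.",
                 class = "dosegain_error_invalid_argument")
  }
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  if (method == "fisher") {
    stats::fisher.test(tab)$p.value
  } else {
    stats::prop.test(c(k1, k2), c(n1, n2))$p.value
  }
}

#' Bullet-arrow chart records
#'
#' Canonical per-patient records for a bullet-arrow chart: patients sorted
#' ascending by supine penalty (the bullet), prone penalty as the arrowhead,
#' arrow direction `"down"` when prone reduces the penalty.
#'
#' @param pairs Paired-score table from [pair_scores()].
#'
#' @return A tibble `rank, patient_id, supine, prone, delta, direction` with
#'   `direction` in `{"down", "up", "tie"}`.
#' @export
bullet_arrow <- function(pairs) {
  if (nrow(pairs) == 0) {
    rlang::abort("No paired scores to chart.",
                 class = "dosegain_error_invalid_argument")
  }
  pairs |>
    dplyr::arrange(.data$supine, .data$patient_id) |>
    dplyr::mutate(
      rank = dplyr::row_number(),
      direction = dplyr::case_when(
        .data$delta < 0 ~ "down",
        .data$delta > 0 ~ "up",
        TRUE ~ "tie"
      )
    ) |>
    dplyr::select("rank", "patient_id", "supine", "prone", "delta", "direction")
}

#' Round half away from zero
#'
#' Decimal rounding as used in clinical reporting (2.5 -> 3, -2.5 -> -3),
#' unlike R's banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
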