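# End-to-end analysis: DVHs + characteristics -> penalties, gain summaries,
# predictor screen, bullet-arrow data, priority-type comparison.

#' Run the full dosimetric-gain pipeline
#'
#' Chains the stages for one or more priority weight sets: per-structure
#' MADDs and penalty scores, paired gain assessment (t-test, exact binomial
#' interval, subgroup split at a supine-penalty threshold), bullet-arrow
#' chart records, a priority-type median table, and — when a characteristics
#' table is supplied — the univariable predictor screen against the penalty
#' difference of the first weight set.
#'
#' @param dvh Long DVH table in percent of prescribed dose (columns
#'   `patient_id, setup, structure, dose, volume`), e.g. from [read_dvh()]
#'   or [generate_cohort()].
#' @param characteristics Optional characteristics table with `patient_id`.
#' @param weight_sets Character vector of built-in set names and/or a list
#'   of [weight_set()] objects; the first set drives the predictor screen.
#' @param split_at Supine-penalty threshold for the subgroup gain split.
#' @param alpha Level of the fractional-polynomial nonlinearity test.
#' @param level Confidence level for binomial intervals.
#' @param exclude_outliers Patient ids excluded from the predictor screen
#'   (they stay in the gain counts, mirroring a sensitivity analysis).
#' @param fp Run nonlinearity checks in the screen.
#' @param outdir Optional directory; when given, writes `penalties.csv`,
#'   `gain_summary.json`, `bullet_arrow.csv`, `table_priorities.csv` and
#'   (if available) `predictors.csv`.
#'
#' @return A list of class `dosegain_report`: `penalties`, `pairs` (first
#'   set), `gains` (one row per weight set), `subgroups`, `subgroup_p`,
#'   `bullet` (first set), `table_priorities`, `predictors` (or `NULL`).
#' @export
run_pipeline <- function(dvh, characteristics = NULL, weight_sets = "type1",
                         split_at = 2, alpha = 0.05, level = 0.95,
                         exclude_outliers = NULL, fp = TRUE, outdir = NULL) {
  if (!is.list(weight_sets) || is.data.frame(weight_sets)) {
    weight_sets <- as.list(weight_sets)
  }
  sets <- purrr::map(weight_sets, as_weight_set)
  set_names <- purrr::map_chr(sets, ~ attr(.x, "name"))

  penalties <- purrr::map(sets, ~ score_cohort(dvh, .x)) |> dplyr::bind_rows()
  pairs_by_set <- penalties |>
    dplyr::group_by(.data$weight_set) |>
    dplyr::group_map(~ pair_scores(.x), .keep = TRUE) |>
    stats::setNames(sort(unique(penalties$weight_set)))
  # group_map sorts groups alphabetically; reorder to the requested order
  pairs_by_set <- pairs_by_set[set_names]

  gains <- purrr::imap(pairs_by_set, function(p, nm) {
    dplyr::mutate(count_gains(p, level = level), weight_set = nm, .before = 1)
  }) |> dplyr::bind_rows()

  first_pairs <- pairs_by_set[[1]]
  # when every patient lies on one side of the threshold there is nothing
  # to split; report the overall summary with an undefined comparison
  split <- tryCatch(
    split_gains(first_pairs, split_at = split_at, level = level),
    dosegain_error_empty_subgroup = function(e) {
      rlang::warn(sprintf(
        "All supine penalties on one side of %g; subgroup split skipped.",
        split_at))
      list(subgroups = NULL, p_value = NA_real_)
    })
  bullet <- bullet_arrow(first_pairs)
  table_priorities <- render_table4(penalties)

  predictors <- NULL
  if (!is.null(characteristics)) {
    analysis <- characteristics |>
      dplyr::inner_join(
        dplyr::rename(first_pairs, supine_score = "supine",
                      prone_score = "prone", delta_penalty = "delta"),
        by = "patient_id")
    predictors <- screen_all(analysis, alpha = alpha, fp = fp,
                             exclude = exclude_outliers)
  }

  report <- structure(list(
    penalties = penalties, pairs = first_pairs, gains = gains,
    subgroups = split$subgroups, subgroup_p = split$p_value,
    bullet = bullet, table_priorities = table_priorities,
    predictors = predictors,
    settings = list(weight_sets = set_names, split_at = split_at,
                    alpha = alpha, level = level,
                    exclude_outliers = exclude_outliers)
  ), class = "dosegain_report")

  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' @export
print.dosegain_report <- function(x, ...) {
  cat("<dosegain_report>\n")
  g <- x$gains
  for (i in seq_len(nrow(g))) {
    cat(sprintf("  %-6s gain %d/%d (%.1f%%, 95%% CI %.1f-%.1f%%)\n",
                g$weight_set[i], g$n_gain[i], g$n[i],
                100 * g$proportion[i], 100 * g$ci_low[i], 100 * g$ci_high[i]))
  }
  cat(sprintf("  subgroup split p = %.3g\n", x$subgroup_p))
  if (!is.null(x$predictors)) {
    cat(sprintf("  predictor screen: %d characteristics, %d significant\n",
                nrow(x$predictors), sum(x$predictors$significant)))
  }
  invisible(x)
}

#' Write a pipeline report bundle to disk
#'
#' @param report A `dosegain_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Named vector of written paths, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    penalties = file.path(dir, "penalties.csv"),
    gains = file.path(dir, "gain_summary.json"),
    bullet = file.path(dir, "bullet_arrow.csv"),
    priorities = file.path(dir, "table_priorities.csv")
  )
  readr::write_csv(report$penalties, paths[["penalties"]])
  jsonlite::write_json(
    list(gains = report$gains, subgroups = report$subgroups,
         subgroup_p = report$subgroup_p, settings = report$settings),
    paths[["gains"]], auto_unbox = TRUE, digits = NA)
  readr::write_csv(report$bullet, paths[["bullet"]])
  readr::write_csv(report$table_priorities, paths[["priorities"]])
  if (!is.null(report$predictors)) {
    paths[["predictors"]] <- file.path(dir, "predictors.csv")
    readr::write_csv(report$predictors, paths[["predictors"]])
  }
  invisible(paths)
}

fmt_med_range <- function(x) {
  f <- function(v) sprintf("%.2f", round_half_up(v, 2))
  sprintf("%s(%s–%s)", f(stats::median(x)), f(min(x)), f(max(x)))
}

#' Median penalty scores per priority type
#'
#' Summarises a scored cohort into the standard priority-type table: median
#' (range) of the supine and prone penalty scores and of their per-patient
#' difference, formatted to two decimals alongside the raw numbers.
#'
#' @param penalties Penalty table from [score_cohort()] (one or several
#'   weight sets stacked).
#'
#' @return A tibble with one row per weight set: numeric medians
#'   (`median_supine`, `median_prone`, `median_delta`) and formatted
#'   `supine`, `prone`, `delta` columns like `"2.36(1.33-4.26)"`.
#' @export
render_table4 <- function(penalties) {
  penalties |>
    dplyr::select("patient_id", "setup", "weight_set", "score") |>
    tidyr::pivot_wider(names_from = "setup", values_from = "score") |>
    dplyr::filter(!is.na(.data$supine), !is.na(.data$prone)) |>
    dplyr::mutate(delta = .data$prone - .data$supine) |>
    dplyr::group_by(.data$weight_set) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_supine = stats::median(.data$supine),
      median_prone = stats::median(.data$prone),
      median_delta = stats::median(.data$delta),
      supine = fmt_med_range(.data$supine),
      prone = fmt_med_range(.data$prone),
      delta = fmt_med_range(.data$delta),
      .groups = "drop"
    )
}
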