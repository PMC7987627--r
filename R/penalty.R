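# Priority-weighted plan penalty scores.
#
# A plan's penalty score is a convex combination of its structures' MADDs,
# Penalty = sum_i w_i M_i with sum_i w_i = 1, so the score lives on the same
# percent-of-prescribed-dose scale as the MADDs and reads as a weighted
# average dose deviation over all organs at risk and targets.

.builtin_weight_table <- function() {
  # order: heart, right lung, left lung, tumor bed, left breast, right breast, body
  structures <- c("heart", "lung_right", "lung_left", "tumor_bed",
                  "breast_left", "breast_right", "body")
  sets <- list(
    type1 = c(0.40, 0.16, 0.14, 0.11, 0.09, 0.10, 0),
    heart = c(0.65, 0.08, 0.07, 0.10, 0.05, 0.05, 0),
    lungs = c(0.20, 0.30, 0.35, 0.07, 0.04, 0.04, 0),
    ptvs  = c(0.15, 0.08, 0.07, 0.35, 0.30, 0.05, 0),
    body  = c(0.10, 0.15, 0.15, 0.08, 0.07, 0.15, 0.30)
  )
  purrr::imap(sets, ~ stats::setNames(.x, structures))
}

#' Construct a validated weight set
#'
#' @param weights Named numeric vector or named list mapping structure name to
#'   a non-negative weight; weights must sum to 1 (tolerance 1e-9).
#' @param name Label for the set (the "priority type").
#'
#' @return A `dosegain_weight_set`: a tibble with columns `structure` and
#'   `weight` and a `name` attribute.
#' @export
weight_set <- function(weights, name = "custom") {
  w <- unlist(weights)
  if (is.null(names(w)) || any(!nzchar(names(w)))) {
    rlang::abort("Weights must be named by structure.",
                 class = "dosegain_error_invalid_argument")
  }
  if (any(w < 0)) {
    rlang::abort("Weights must be non-negative.",
                 class = "dosegain_error_invalid_argument")
  }
  if (abs(sum(w) - 1) > 1e-9) {
    rlang::abort(sprintf("Weights must sum to 1 (got %.12f).", sum(w)),
                 class = "dosegain_error_invalid_argument")
  }
  out <- tibble::tibble(structure = names(w), weight = unname(w))
  attr(out, "name") <- name
  class(out) <- c("dosegain_weight_set", class(out))
  out
}

#' Built-in priority weight sets
#'
#' Five named priority types expressing different clinical emphases:
#' `type1` (heart-first general practice), `heart` (cardiac comorbidity),
#' `lungs` (pulmonary risk), `ptvs` (target-coverage priority) and `body`
#' (whole-body low-dose / second-cancer concern; the only set that weights
#' the external body contour, which is otherwise 0 so organs and targets are
#' not double-counted).
#'
#' @param name One of `"type1"`, `"heart"`, `"lungs"`, `"ptvs"`, `"body"`.
#'
#' @return A [weight_set()].
#' @export
#'
#' @examples
#' builtin_weights("type1")
builtin_weights <- function(name = c("type1", "heart", "lungs", "ptvs", "body")) {
  tab <- .builtin_weight_table()
  if (length(name) != 1 || !name %in% names(tab)) {
    rlang::abort(paste0("Unknown weight set '", paste(name, collapse = "/"),
                        "'; built-ins are: ", paste(names(tab), collapse = ", ")),
                 class = "dosegain_error_lookup")
  }
  weight_set(tab[[name]], name = name)
}

as_weight_set <- function(ws) {
  if (inherits(ws, "dosegain_weight_set")) return(ws)
  if (is.character(ws) && length(ws) == 1) return(builtin_weights(ws))
  if (is.data.frame(ws) && all(c("structure", "weight") %in% names(ws))) {
    return(weight_set(stats::setNames(ws$weight, ws$structure),
                      name = attr(ws, "name") %||% "custom"))
  }
  weight_set(ws)
}

#' Read a weight-set configuration file
#'
#' YAML or JSON with a `name` field and a `weights` map from structure to
#' weight; validated on load.
#'
#' @param path Config file path (`.yaml`, `.yml` or `.json`).
#' @return A [weight_set()].
#' @export
read_weight_set <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$weights)) {
    rlang::abort("Weight-set config must contain a `weights` map.",
                 class = "dosegain_error_invalid_argument")
  }
  weight_set(cfg$weights, name = cfg$name %||% "custom")
}

#' Penalty score of one plan from its structure MADDs
#'
#' @param madds Named numeric vector (or single-plan tibble with columns
#'   `structure`, `madd`) of per-structure MADDs in percent of prescribed
#'   dose.
#' @param weights A [weight_set()], a built-in set name, or a named numeric
#'   vector of weights.
#' @param renormalize_missing If `TRUE`, structures with positive weight that
#'   are absent from `madds` are dropped and the remaining weights rescaled
#'   to sum to 1 (with a warning); by default a missing weighted structure is
#'   an error.
#'
#' @return A single numeric score (percent of prescribed dose), lying between
#'   the smallest and largest weighted MADD.
#' @export
#'
#' @examples
#' penalty_score(c(heart = 1, lung_right = 0, lung_left = 0, tumor_bed = 0,
#'                 breast_left = 0, breast_right = 0), "heart")
penalty_score <- function(madds, weights = "type1", renormalize_missing = FALSE) {
  ws <- as_weight_set(weights)
  if (is.data.frame(madds)) {
    madds <- stats::setNames(madds$madd, madds$structure)
  }
  active <- ws$structure[ws$weight > 0]
  missing <- setdiff(active, names(madds))
  w <- stats::setNames(ws$weight, ws$structure)
  if (length(missing) > 0) {
    if (!renormalize_missing) {
      rlang::abort(paste0("MADD missing for weighted structure(s): ",
                          paste(missing, collapse = ", ")),
                   class = "dosegain_error_missing_structure")
    }
    rlang::warn(paste0("Renormalizing weights over missing structure(s): ",
                       paste(missing, collapse = ", ")))
    w <- w[setdiff(names(w), missing)]
    w <- w / sum(w)
    active <- setdiff(active, missing)
  }
  sum(w[active] * madds[active])
}

#' Score a cohort DVH table under a weight set
#'
#' Batch driver: computes per-structure MADDs with [compute_madds()] and
#' rolls them into one penalty score per patient and setup. Patients lacking
#' one of the two setups are excluded with a warning (their plan pair is not
#' comparable).
#'
#' @param data Long DVH table (`patient_id`, `setup`, `structure`, `dose`,
#'   `volume`) in percent of prescribed dose.
#' @param weights A [weight_set()] or built-in set name.
#' @param references Per-structure reference doses, see [default_references()].
#' @param renormalize_missing Passed to [penalty_score()].
#'
#' @return A tibble with one row per patient/setup: `patient_id`, `setup`,
#'   `weight_set`, `score`, and one `<structure>_madd` column per structure.
#' @export
score_cohort <- function(data, weights = "type1",
                         references = default_references(),
                         renormalize_missing = FALSE) {
  ws <- as_weight_set(weights)
  madds <- compute_madds(data, references)

  both <- madds |>
    dplyr::distinct(.data$patient_id, .data$setup) |>
    dplyr::count(.data$patient_id) |>
    dplyr::filter(.data$n == 2)
  dropped <- setdiff(unique(madds$patient_id), both$patient_id)
  if (length(dropped) > 0) {
    rlang::warn(paste0("Excluding patient(s) without both setups: ",
                       paste(dropped, collapse = ", ")))
    madds <- dplyr::filter(madds, .data$patient_id %in% both$patient_id)
  }

  scores <- madds |>
    dplyr::group_by(.data$patient_id, .data$setup) |>
    dplyr::summarise(
      score = penalty_score(stats::setNames(.data$madd, .data$structure), ws,
                            renormalize_missing = renormalize_missing),
      .groups = "drop"
    )

  wide <- madds |>
    dplyr::mutate(structure = paste0(.data$structure, "_madd")) |>
    tidyr::pivot_wider(names_from = "structure", values_from = "madd")

  scores |>
    dplyr::mutate(weight_set = attr(ws, "name"), .after = "setup") |>
    dplyr::left_join(wide, by = c("patient_id", "setup")) |>
    dplyr::arrange(.data$patient_id, .data$setup)
}
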