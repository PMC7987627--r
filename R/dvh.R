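# Cumulative dose-volume histograms and the mean absolute dose deviation.
#
# A cumulative DVH gives, for each dose level D, the structure volume that
# receives at least D. All pipeline math runs in percent of the prescribed
# dose; conversion happens at ingestion.

#' Structures recognised by the pipeline
#'
#' The seven structures of a left-sided whole-breast plan: the heart, both
#' lungs, both breasts, the tumor bed and the external body contour.
#'
#' @return Character vector of structure names.
#' @export
dvh_structures <- function() {
  c("heart", "lung_left", "lung_right", "breast_left", "breast_right",
    "tumor_bed", "body")
}

#' Default reference doses per structure
#'
#' The MADD of a structure is measured against a reference dose: 0 for an
#' organ at risk (any dose is unwanted) and the prescribed dose for a target
#' volume (deviation in either direction is unwanted). For a left-sided
#' treatment the ipsilateral breast and the tumor bed are targets; heart,
#' lungs, contralateral breast and body are organs at risk.
#'
#' @param prescribed_dose Reference dose assigned to target structures, in the
#'   unit the DVHs use. Defaults to 100, i.e. DVHs in percent of the
#'   prescribed dose.
#' @param target_structures Character vector of structures referenced to
#'   `prescribed_dose` rather than 0.
#'
#' @return A tibble with columns `structure` and `reference`.
#' @export
default_references <- function(prescribed_dose = 100,
                               target_structures = c("breast_left", "tumor_bed")) {
  tibble::tibble(
    structure = dvh_structures(),
    reference = ifelse(dvh_structures() %in% target_structures,
                       prescribed_dose, 0)
  )
}

#' Canonicalize a single cumulative DVH curve
#'
#' Sorts by dose, merges duplicated dose rows (keeping the smaller cumulative
#' volume, since a cumulative DVH is a right-continuous step function), and
#' validates the invariants: volumes non-negative and non-increasing, doses
#' non-negative. If `total_volume` is supplied and the first tabulated volume
#' falls short of it (a truncated export), a point (dose 0, total_volume) is
#' prepended, because by definition the whole structure receives at least
#' dose 0.
#'
#' @param data Data frame with numeric columns `dose` and `volume` for one
#'   structure.
#' @param total_volume Optional structure volume V0. Defaults to the largest
#'   tabulated cumulative volume.
#'
#' @return A tibble with columns `dose` and `volume`, doses strictly
#'   increasing, volumes non-increasing, first volume equal to V0.
#' @export
as_dvh <- function(data, total_volume = NULL) {
  if (!all(c("dose", "volume") %in% names(data))) {
    rlang::abort("`data` must have columns `dose` and `volume`.",
                 class = "dosegain_error_invalid_dvh")
  }
  dose <- as.numeric(data$dose)
  volume <- as.numeric(data$volume)
  if (anyNA(dose) || anyNA(volume)) {
    rlang::abort("DVH contains missing dose or volume values.",
                 class = "dosegain_error_invalid_dvh")
  }
  if (any(dose < 0) || any(volume < 0)) {
    rlang::abort("DVH doses and volumes must be non-negative.",
                 class = "dosegain_error_invalid_dvh")
  }
  ord <- order(dose, volume)
  dose <- dose[ord]
  volume <- volume[ord]
  # duplicate doses: keep the smaller cumulative volume (step-function value);
  # rows are sorted by volume within dose, so the first occurrence is it
  keep <- !duplicated(dose)
  dose <- dose[keep]
  volume <- volume[keep]
  if (is.unsorted(rev(volume))) {
    rlang::abort("Cumulative volumes must be non-increasing in dose.",
                 class = "dosegain_error_invalid_dvh")
  }
  v0 <- if (is.null(total_volume)) volume[1] else as.numeric(total_volume)
  if (v0 < volume[1]) {
    rlang::abort("`total_volume` is smaller than the largest tabulated volume.",
                 class = "dosegain_error_invalid_dvh")
  }
  if (volume[1] < v0 * (1 - 1e-6) && dose[1] > 0) {
    dose <- c(0, dose)
    volume <- c(v0, volume)
  }
  out <- tibble::tibble(dose = dose, volume = volume)
  attr(out, "total_volume") <- v0
  out
}

#' Convert a DVH dose axis to percent of the prescribed dose
#'
#' @param data Data frame with a `dose` column in absolute units (Gy).
#' @param prescribed_dose Prescription dose in the same absolute unit; must be
#'   positive.
#'
#' @return `data` with `dose` replaced by `100 * dose / prescribed_dose`.
#' @export
#'
#' @examples
#' dvh_to_relative(data.frame(dose = c(0, 23.625, 47.25), volume = c(1, .5, 0)),
#'                 prescribed_dose = 47.25)
dvh_to_relative <- function(data, prescribed_dose) {
  if (!is.numeric(prescribed_dose) || length(prescribed_dose) != 1 ||
      !is.finite(prescribed_dose) || prescribed_dose <= 0) {
    rlang::abort("`prescribed_dose` must be a single positive number.",
                 class = "dosegain_error_invalid_argument")
  }
  data$dose <- 100 * data$dose / prescribed_dose
  data
}

#' Differential volumes of a cumulative DVH
#'
#' Decomposes a cumulative curve into rectangular strips: point j (j < n)
#' carries the volume \eqn{\delta V_j = V_j - V_{j+1}} at dose \eqn{D_j}, and
#' the terminal point carries its full remaining volume \eqn{V_n} at
#' \eqn{D_n} (no extrapolation beyond the tabulated maximum dose). The strip
#' volumes sum to the structure volume V0 by construction.
#'
#' @param data A single cumulative DVH (columns `dose`, `volume`); it is
#'   canonicalized with [as_dvh()] first.
#'
#' @return A tibble with columns `dose` and `dvol`.
#' @export
differential_volumes <- function(data) {
  dvh <- as_dvh(data)
  n <- nrow(dvh)
  dvol <- c(dvh$volume[-n] - dvh$volume[-1], dvh$volume[n])
  tibble::tibble(dose = dvh$dose, dvol = dvol)
}

# strip-sum MADD on already-canonical dose/volume vectors (hot path)
madd_strips <- function(dose, volume, reference) {
  n <- length(dose)
  dvol <- c(volume[-n] - volume[-1], volume[n])
  sum(abs(dose - reference) * dvol) / volume[1]
}

#' Mean absolute dose deviation (MADD) of a structure
#'
#' The MADD is the volume-weighted mean of |D - A| over the structure, where
#' A is the reference dose: \deqn{M = \int_0^{V_0} |D - A| / V_0 \, dV,}
#' evaluated on the cumulative DVH by left-anchored rectangular strips
#' \deqn{M = \sum_j |D_j - A| \, \delta V_j / V_0.} With A = 0 the MADD is
#' the structure's mean dose. The unit is the dose unit of the DVH; the
#' strip approximation is exact for step-function DVHs and biased by at most
#' one dose-grid width otherwise.
#'
#' @param data A single cumulative DVH (columns `dose`, `volume`).
#' @param reference Reference dose A in the same unit as the DVH doses: 0 for
#'   an organ at risk, the prescribed dose for a target.
#'
#' @return A non-negative scalar dose deviation.
#' @export
#'
#' @examples
#' # half the volume at 10%, half at 30%, reference 0: MADD = mean dose = 20%
#' madd(data.frame(dose = c(10, 30), volume = c(1, 0.5)), reference = 0)
madd <- function(data, reference = 0) {
  if (!is.numeric(reference) || length(reference) != 1 ||
      !is.finite(reference) || reference < 0) {
    rlang::abort("`reference` must be a single non-negative dose.",
                 class = "dosegain_error_invalid_argument")
  }
  dvh <- as_dvh(data)
  if (attr(dvh, "total_volume") <= 0) {
    rlang::abort("Structure has zero volume; MADD is undefined.",
                 class = "dosegain_error_degenerate_structure")
  }
  madd_strips(dvh$dose, dvh$volume, reference)
}

#' Per-structure MADDs for a cohort DVH table
#'
#' Applies [madd()] to every (patient, setup, structure) curve of a long DVH
#' table, against per-structure reference doses.
#'
#' @param data Long DVH table with columns `patient_id`, `setup`,
#'   `structure`, `dose`, `volume`, doses in percent of the prescribed dose.
#' @param references Tibble mapping `structure` to `reference` dose;
#'   defaults to [default_references()].
#'
#' @return A tibble with one row per patient/setup/structure and columns
#'   `patient_id`, `setup`, `structure`, `madd`.
#' @export
compute_madds <- function(data, references = default_references()) {
  required <- c("patient_id", "setup", "structure", "dose", "volume")
  if (!all(required %in% names(data))) {
    rlang::abort(paste("DVH table must have columns",
                       paste(required, collapse = ", ")),
                 class = "dosegain_error_invalid_argument")
  }
  unknown <- setdiff(unique(data$structure), references$structure)
  if (length(unknown) > 0) {
    rlang::abort(paste0("No reference dose for structure(s): ",
                        paste(unknown, collapse = ", ")),
                 class = "dosegain_error_invalid_argument")
  }
  data |>
    dplyr::inner_join(references, by = "structure") |>
    dplyr::arrange(.data$patient_id, .data$setup, .data$structure, .data$dose) |>
    dplyr::group_by(.data$patient_id, .data$setup, .data$structure) |>
    dplyr::summarise(
      madd = madd_strips(.data$dose, .data$volume, .data$reference[1]),
      .groups = "drop"
    )
}

#' Read a cohort DVH table from CSV
#'
#' Expects the dialect `patient_id,setup,structure,dose,volume` with an
#' optional metadata comment line `# dose_unit=Gy` or `# dose_unit=percent`.
#' Doses in Gy are converted to percent of `prescribed_dose` on ingestion, so
#' downstream computation is always in relative dose.
#'
#' @param path CSV file path.
#' @param prescribed_dose Prescription in Gy, required when the file declares
#'   `dose_unit=Gy`.
#'
#' @return A tibble `patient_id, setup, structure, dose, volume` with doses in
#'   percent of the prescribed dose.
#' @export
read_dvh <- function(path, prescribed_dose = NULL) {
  header <- readLines(path, n = 20L)
  unit_line <- grep("^#\\s*dose_unit\\s*=", header, value = TRUE)
  dose_unit <- if (length(unit_line) > 0) {
    trimws(sub("^#\\s*dose_unit\\s*=", "", unit_line[1]))
  } else {
    "percent"
  }
  if (!dose_unit %in% c("Gy", "percent")) {
    rlang::abort(paste0("Unknown dose_unit '", dose_unit, "' in ", path),
                 class = "dosegain_error_unit")
  }
  out <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(
                           patient_id = readr::col_character(),
                           setup = readr::col_character(),
                           structure = readr::col_character(),
                           dose = readr::col_double(),
                           volume = readr::col_double()
                         ))
  bad <- setdiff(unique(out$setup), c("prone", "supine"))
  if (length(bad) > 0) {
    rlang::abort(paste0("Unknown setup value(s): ", paste(bad, collapse = ", ")),
                 class = "dosegain_error_invalid_argument")
  }
  if (dose_unit == "Gy") {
    if (is.null(prescribed_dose)) {
      rlang::abort("File is in Gy; supply `prescribed_dose` to convert.",
                   class = "dosegain_error_unit")
    }
    out <- dvh_to_relative(out, prescribed_dose)
  }
  out
}

#' Write a cohort DVH table to CSV
#'
#' @param data DVH table as returned by [read_dvh()] or [generate_cohort()].
#' @param path Output CSV path.
#' @param dose_unit Unit recorded in the `# dose_unit=` metadata line.
#' @return `path`, invisibly.
#' @export
write_dvh <- function(data, path, dose_unit = "percent") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# dose_unit=", dose_unit), con)
  utils::write.table(
    data[, c("patient_id", "setup", "structure", "dose", "volume")],
    con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a treatment-planning-system DVH text export
#'
#' Parses the common block-per-structure export: each block starts with a
#' line `Structure: <name>` and contains a two-column numeric table of dose
#' and cumulative volume (absolute or relative; relative volumes expressed in
#' percent are rescaled to fractions). Non-numeric lines inside a block
#' (column headers, blank lines) are skipped.
#'
#' @param path Text export path.
#' @param patient_id,setup Identifiers attached to every parsed curve.
#'
#' @return A tibble `patient_id, setup, structure, dose, volume`.
#' @export
read_dvh_export <- function(path, patient_id = "unknown", setup = "supine") {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^\\s*Structure\\s*:", lines)
  if (length(starts) == 0) {
    rlang::abort("No 'Structure:' blocks found in export.",
                 class = "dosegain_error_invalid_argument")
  }
  ends <- c(starts[-1] - 1L, length(lines))
  blocks <- purrr::map2(starts, ends, function(s, e) {
    name <- trimws(sub("^\\s*Structure\\s*:", "", lines[s]))
    body <- lines[(s + 1L):e]
    rows <- regmatches(body, gregexpr("[-+]?[0-9]*\\.?[0-9]+(?:[eE][-+]?[0-9]+)?", body))
    num <- purrr::keep(rows, ~ length(.x) >= 2)
    if (length(num) == 0) return(NULL)
    dose <- as.numeric(purrr::map_chr(num, 1))
    volume <- as.numeric(purrr::map_chr(num, 2))
    # percent-volume exports: rescale so volumes are fractions of V0
    if (max(volume) > 1 && max(volume) <= 100.5) volume <- volume / 100
    tibble::tibble(patient_id = patient_id, setup = setup,
                   structure = name, dose = dose, volume = volume)
  })
  dplyr::bind_rows(blocks)
}
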