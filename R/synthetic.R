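# Synthetic paired prone/supine cohorts.
#
# Voxel-level structure doses are drawn from two-component mixtures (an
# in-field plateau near the prescription for target tissue, plus an
# exponentially decaying out-of-field tail), rolled up to cumulative DVHs on
# a fixed grid, so every downstream stage exercises the same code path as
# clinical DVH exports. Patient characteristics are sampled to mimic a
# typical left-breast dual-planning cohort, and breast pendulousness (the
# prone/supine depth ratio) drives the prone ipsilateral-lung dose through
# the dose model itself, planting a recoverable characteristic-to-gain link.

default_dose_models <- function() {
  # percent-of-prescribed-dose units; in_field is the baseline in-field
  # voxel fraction, plateau the in-field dose level, out_scale the mean of
  # the out-of-field exponential tail, patient_sd the log-sd of the mean-one
  # per-patient lognormal factor on the in-field fraction.
  tibble::tribble(
    ~structure, ~setup, ~in_field, ~plateau, ~plateau_sd, ~out_scale, ~patient_sd,
    "heart", "supine", 0.019, 55, 8, 0.90, 0.35,
    "heart", "prone", 0.046, 55, 8, 0.90, 0.35,
    "lung_left", "supine", 0.113, 62, 8, 0.90, 0.35,
    "lung_left", "prone", 0.014, 55, 8, 0.90, 0.35,
    "lung_right", "supine", 0.000, 55, 8, 0.50, 0.35,
    "lung_right", "prone", 0.000, 55, 8, 0.80, 0.35,
    "breast_right", "supine", 0.000, 55, 8, 0.80, 0.35,
    "breast_right", "prone", 0.000, 55, 8, 1.70, 0.35,
    "breast_left", "supine", 1.000, 100.0, 3.5, 0.00, 0.00,
    "breast_left", "prone", 1.000, 99.3, 3.9, 0.00, 0.00,
    "tumor_bed", "supine", 1.000, 100.6, 2.5, 0.00, 0.00,
    "tumor_bed", "prone", 1.000, 100.2, 2.9, 0.00, 0.00,
    "body", "supine", 0.035, 95, 10, 1.20, 0.35,
    "body", "prone", 0.030, 95, 10, 1.00, 0.35
  )
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate a 116-patient left-breast dual-planning cohort: per
#' structure and setup a two-component voxel dose mixture calibrated so that
#' cohort-mean MADDs land near typical clinical values (ipsilateral lung
#' about 7.6% of prescribed dose supine versus 1.9% prone; heart about 1.9%
#' supine versus 3.4% prone; contralateral breast 0.8% versus 1.7%), and
#' characteristic distributions matching published cohort medians and ranges
#' (breast volume median about 484 mL, BMI median 25, age median 57.5).
#' Pendulousness enters the dose model: the prone ipsilateral-lung in-field
#' fraction shrinks as `(ratio_ref / depth_ratio)^kappa`, so patients whose
#' breast sags more gain more from prone positioning.
#'
#' @param n_patients Number of paired patients.
#' @param seed Integer seed; the generator is deterministic given
#'   `(config, seed)`.
#' @param n_voxels Voxel sample size per structure (default 10000; keeps the
#'   DVH grid bias on the MADD below about 0.1% dose).
#' @param grid_width DVH dose-grid width in percent of prescribed dose.
#' @param link_mode `"dose"` plants the characteristic-gain link through the
#'   voxel dose model; `"direct"` skips voxel simulation and draws the
#'   penalty difference as an explicit linear function of the depth ratio
#'   (fast mode for regression-recovery studies).
#' @param link_slope,link_intercept,link_noise_sd,link_supine_coef
#'   Direct-mode linear link: `delta = intercept + slope * depth_ratio +
#'   supine_coef * (supine - 2.45) + N(0, noise_sd)`; the supine term plants
#'   the observed baseline dependence (patients with a high supine penalty
#'   gain more from prone).
#' @param kappa,ratio_ref Dose-mode link: exponent and reference ratio of the
#'   prone ipsilateral-lung in-field attenuation.
#' @param dose_models Data frame of per-structure mixture parameters (see
#'   `default_dose_models` in the package source).
#'
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 116, seed = 1, n_voxels = 10000,
                          grid_width = 0.1, link_mode = c("dose", "direct"),
                          link_slope = -0.795, link_intercept = 1.244,
                          link_noise_sd = 0.5, link_supine_coef = -0.35,
                          kappa = 3, ratio_ref = 1.9,
                          dose_models = default_dose_models()) {
  link_mode <- match.arg(link_mode)
  stopifnot(n_patients >= 1, n_voxels >= 100, grid_width > 0,
            all(dose_models$in_field >= 0 & dose_models$in_field <= 1))
  structure(list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    n_voxels = as.integer(n_voxels), grid_width = grid_width,
    link_mode = link_mode, link_slope = link_slope,
    link_intercept = link_intercept, link_noise_sd = link_noise_sd,
    link_supine_coef = link_supine_coef,
    kappa = kappa, ratio_ref = ratio_ref, dose_models = dose_models
  ), class = "cohort_config")
}

# run `code` under a local RNG stream, leaving the caller's RNG untouched
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Build a cumulative DVH from a voxel dose sample
#'
#' Bins doses on a regular grid and tabulates, at each grid dose, the
#' fraction of voxels receiving at least that dose. Trailing zero-volume
#' grid points are dropped.
#'
#' @param doses Non-negative voxel doses (percent of prescribed dose).
#' @param grid_width Grid spacing in the same unit.
#'
#' @return A tibble `dose, volume` with `volume` as a fraction of the
#'   structure (first volume 1).
#' @export
dvh_from_doses <- function(doses, grid_width = 0.1) {
  if (length(doses) == 0 || any(doses < 0)) {
    rlang::abort("Need a non-empty, non-negative dose sample.",
                 class = "dosegain_error_invalid_argument")
  }
  idx <- floor(doses / grid_width)
  nbin <- max(idx) + 1L
  counts <- tabulate(idx + 1L, nbins = nbin)
  vol <- rev(cumsum(rev(counts))) / length(doses)
  keep <- vol > 0
  tibble::tibble(dose = (seq_len(nbin)[keep] - 1) * grid_width,
                 volume = vol[keep])
}

#' Draw a voxel dose sample for one structure and setup
#'
#' Mixture draw: a Binomial share of in-field voxels at a truncated-normal
#' plateau dose, the remainder on an exponential out-of-field tail.
#'
#' @param config A [cohort_config()].
#' @param structure,setup Which dose model to use.
#' @param in_field_factor,out_factor,plateau_shift Per-patient modifiers of
#'   the in-field fraction, tail scale and plateau level.
#' @param n_voxels Sample size (defaults to the config's).
#'
#' @return Numeric vector of voxel doses in percent of prescribed dose.
#' @export
simulate_structure_doses <- function(config, structure, setup,
                                     in_field_factor = 1, out_factor = 1,
                                     plateau_shift = 0,
                                     n_voxels = config$n_voxels) {
  m <- config$dose_models[config$dose_models$structure == structure &
                            config$dose_models$setup == setup, ]
  if (nrow(m) != 1) {
    rlang::abort(paste0("No dose model for ", structure, "/", setup, "."),
                 class = "dosegain_error_config")
  }
  f <- min(m$in_field * in_field_factor, 1)
  n_in <- stats::rbinom(1, n_voxels, f)
  d_in <- if (n_in > 0) {
    pmax(stats::rnorm(n_in, m$plateau + plateau_shift, m$plateau_sd), 0)
  } else {
    numeric(0)
  }
  scale <- m$out_scale * out_factor
  d_out <- if (n_voxels - n_in > 0) {
    if (scale > 0) stats::rexp(n_voxels - n_in, rate = 1 / scale)
    else rep(0, n_voxels - n_in)
  } else {
    numeric(0)
  }
  c(d_in, d_out)
}

# mean-one lognormal factor
rlnorm1 <- function(n, sdlog) stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)

sample_characteristics <- function(config) {
  n <- config$n_patients
  z_pend <- stats::rnorm(n)
  z_vol <- stats::rnorm(n)
  depth_ratio <- config$ratio_ref * exp(0.25 * z_pend)
  breast_depth_supine <- round(45 * exp(0.30 * stats::rnorm(n)))
  breast_depth_prone <- round(breast_depth_supine * depth_ratio)
  breast_volume_left <- round(484 * exp(0.65 * (0.45 * z_pend + 0.893 * z_vol)))
  breast_volume_right <- round(breast_volume_left * exp(0.21 + 0.35 * stats::rnorm(n)))
  weight <- round(67 * exp(0.18 * (0.5 * z_vol + 0.866 * stats::rnorm(n))))
  height <- round(stats::rnorm(n, 162, 6.5))
  age <- round(pmin(pmax(stats::rnorm(n, 57.5, 10), 36), 82))
  heart_volume <- round(pmin(pmax(stats::rnorm(n, 461, 90), 259), 687))
  lung_volume_left <- round(pmax(stats::rnorm(n, 2.9, 0.45), 1.3), 1)
  lung_volume_right <- round(pmax(stats::rnorm(n, 3.4, 0.50), 1.5), 1)
  lad_chest_distance <- round(10 * exp(0.5 * stats::rnorm(n)))
  tumor_location <- sample(
    c("lower_inner", "central", "upper_inner", "upper_outer", "lower_outer", "other"),
    n, replace = TRUE, prob = c(0.017, 0.034, 0.095, 0.491, 0.069, 0.294))
  couch <- sample(c("bionix", "varian"), n, replace = TRUE, prob = c(0.853, 0.147))
  preference <- sample(c("supine", "none", "prone"), n, replace = TRUE,
                       prob = c(0.526, 0.179, 0.295))
  # missingness as in retrospective charts: some weights, heights, preferences
  weight[stats::runif(n) < 0.078] <- NA
  height[stats::runif(n) < 0.110] <- NA
  preference[stats::runif(n) < 0.328] <- NA
  tibble::tibble(
    patient_id = sprintf("P%03d", seq_len(n)),
    age = age, height = height, weight = weight,
    bmi = round(weight / (height / 100)^2, 1),
    tumor_location = tumor_location,
    breast_volume_left = breast_volume_left,
    breast_volume_right = breast_volume_right,
    breast_depth_prone = breast_depth_prone,
    breast_depth_supine = breast_depth_supine,
    depth_ratio = depth_ratio,
    heart_volume = heart_volume,
    lung_volume_left = lung_volume_left,
    lung_volume_right = lung_volume_right,
    lung_volume_total = lung_volume_left + lung_volume_right,
    lad_chest_distance = lad_chest_distance,
    couch = couch, preference = preference
  )
}

#' Generate a paired prone/supine synthetic cohort
#'
#' In `"dose"` mode (the default), draws per-patient voxel dose samples for
#' all seven structures in both setups, converts them to cumulative DVHs and
#' returns them alongside the sampled characteristics; the prone
#' ipsilateral-lung dose shrinks with the patient's depth ratio, so the
#' dosimetric gain emerges from the dose model rather than being pasted onto
#' the scores. In `"direct"` mode, penalty scores and their difference are
#' drawn from an explicit linear link on the depth ratio (no DVHs), which is
#' orders of magnitude faster and gives an exactly known planted slope.
#'
#' @param config A [cohort_config()].
#'
#' @return A list of class `synthetic_cohort` with elements
#'   `characteristics` (tibble), `dvh` (long DVH tibble in percent dose, or
#'   `NULL` in direct mode), `scores` (direct mode only: tibble
#'   `patient_id, setup, score`), `truth` (planted generator parameters) and
#'   `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  with_local_seed(config$seed, {
    chars <- sample_characteristics(config)
    n <- config$n_patients
    if (config$link_mode == "direct") {
      supine <- pmax(stats::rnorm(n, 2.45, 0.45), 1.2)
      # baseline dependence: patients with a high supine penalty have more
      # room to gain from prone, as seen on bullet-arrow charts
      delta <- config$link_intercept + config$link_slope * chars$depth_ratio +
        config$link_supine_coef * (supine - 2.45) +
        stats::rnorm(n, 0, config$link_noise_sd)
      scores <- tibble::tibble(
        patient_id = rep(chars$patient_id, each = 2),
        setup = rep(c("supine", "prone"), n),
        score = as.numeric(rbind(supine, supine + delta))
      )
      truth <- list(link_mode = "direct", slope = config$link_slope,
                    intercept = config$link_intercept,
                    noise_sd = config$link_noise_sd)
      out <- list(characteristics = chars, dvh = NULL, scores = scores,
                  truth = truth, config = config)
    } else {
      models <- config$dose_models
      curves <- vector("list", n * nrow(models))
      k <- 0L
      for (i in seq_len(n)) {
        lung_link <- (config$ratio_ref / chars$depth_ratio[i])^config$kappa
        for (r in seq_len(nrow(models))) {
          m <- models[r, ]
          in_factor <- if (m$patient_sd > 0) rlnorm1(1, m$patient_sd) else 1
          if (m$structure == "lung_left" && m$setup == "prone") {
            in_factor <- in_factor * lung_link
          }
          out_factor <- if (m$out_scale > 0) rlnorm1(1, 0.20) else 1
          shift <- if (m$in_field == 1) stats::rnorm(1, 0, 0.8) else 0
          doses <- simulate_structure_doses(config, m$structure, m$setup,
                                            in_field_factor = in_factor,
                                            out_factor = out_factor,
                                            plateau_shift = shift)
          dvh <- dvh_from_doses(doses, config$grid_width)
          k <- k + 1L
          curves[[k]] <- tibble::tibble(
            patient_id = chars$patient_id[i], setup = m$setup,
            structure = m$structure, dose = dvh$dose, volume = dvh$volume)
        }
      }
      truth <- list(link_mode = "dose", kappa = config$kappa,
                    ratio_ref = config$ratio_ref,
                    dose_models = config$dose_models)
      out <- list(characteristics = chars, dvh = dplyr::bind_rows(curves),
                  scores = NULL, truth = truth, config = config)
    }
    class(out) <- "synthetic_cohort"
    out
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients, %s link, seed %d\n",
              x$config$n_patients, x$config$link_mode, x$config$seed))
  if (!is.null(x$dvh)) {
    cat(sprintf("  DVH table: %d rows over %d curves\n", nrow(x$dvh),
                nrow(dplyr::distinct(x$dvh, .data$patient_id, .data$setup,
                                     .data$structure))))
  }
  invisible(x)
}

#' Plant gross outliers in an analysis table
#'
#' Emulates the occasional patient whose prone plan is much worse than the
#' paired supine plan despite unremarkable anatomy: `k` randomly chosen
#' patients get their penalty difference shifted up by `magnitude` (the
#' prone score is shifted accordingly when present) and their depth ratio
#' forced below 1.5 (prone depth recomputed when present). The chosen ids
#' are recorded in the `outlier_ids` attribute.
#'
#' @param data Analysis table with `patient_id` and `delta_penalty` columns
#'   (e.g. the join of characteristics and paired scores).
#' @param k Number of outliers; must be smaller than the number of rows.
#' @param magnitude Upward shift of `delta_penalty`, percent of prescribed
#'   dose.
#' @param seed Optional seed for the choice of patients.
#'
#' @return `data` modified, with attribute `outlier_ids`.
#' @export
plant_outliers <- function(data, k = 3, magnitude = 5, seed = NULL) {
  if (!all(c("patient_id", "delta_penalty") %in% names(data))) {
    rlang::abort("`data` needs `patient_id` and `delta_penalty` columns.",
                 class = "dosegain_error_invalid_argument")
  }
  if (k >= nrow(data)) {
    rlang::abort("`k` must be smaller than the number of patients.",
                 class = "dosegain_error_invalid_argument")
  }
  if (k == 0) {
    attr(data, "outlier_ids") <- character(0)
    return(data)
  }
  pick <- function() sort(sample(nrow(data), k))
  idx <- if (is.null(seed)) pick() else with_local_seed(seed, pick())
  ratio <- if (is.null(seed)) stats::runif(k, 1.1, 1.45) else {
    with_local_seed(seed + 1L, stats::runif(k, 1.1, 1.45))
  }
  data$delta_penalty[idx] <- data$delta_penalty[idx] + magnitude
  if ("prone_score" %in% names(data)) {
    data$prone_score[idx] <- data$prone_score[idx] + magnitude
  }
  if ("depth_ratio" %in% names(data)) {
    data$depth_ratio[idx] <- ratio
    if (all(c("breast_depth_supine", "breast_depth_prone") %in% names(data))) {
      data$breast_depth_prone[idx] <- round(data$breast_depth_supine[idx] * ratio)
      data$delta_depth <- NULL # stale if previously derived
    }
  }
  attr(data, "outlier_ids") <- data$patient_id[idx]
  data
}

#' Write a synthetic cohort to disk
#'
#' Emits the DVH CSV (percent dose) or, in direct mode, a penalty-score CSV,
#' plus the characteristics CSV and a JSON manifest of the planted truths.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#'
#' @return Named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(characteristics = file.path(dir, "characteristics.csv"),
             manifest = file.path(dir, "manifest.json"))
  readr::write_csv(cohort$characteristics, paths[["characteristics"]])
  if (!is.null(cohort$dvh)) {
    paths[["dvh"]] <- file.path(dir, "dvh.csv")
    write_dvh(cohort$dvh, paths[["dvh"]], dose_unit = "percent")
  }
  if (!is.null(cohort$scores)) {
    paths[["scores"]] <- file.path(dir, "scores.csv")
    readr::write_csv(cohort$scores, paths[["scores"]])
  }
  manifest <- cohort$truth
  manifest$n_patients <- cohort$config$n_patients
  manifest$seed <- cohort$config$seed
  manifest$dose_models <- NULL
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
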