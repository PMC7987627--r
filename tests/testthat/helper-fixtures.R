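# Fixtures built in code: random valid DVHs and voxel-level oracles.

# random cumulative DVH: decreasing volumes over an increasing dose grid
rand_dvh <- function(n_points = 40, max_dose = 110, v0 = 1) {
  dose <- sort(runif(n_points, 0, max_dose))
  dose[1] <- 0
  vol <- v0 * c(1, sort(runif(n_points - 1), decreasing = TRUE) * runif(1, 0.3, 1))
  tibble::tibble(dose = dose, volume = vol)
}

# voxel sample -> exact step-function DVH (volumes = fraction >= each dose)
dvh_from_voxels_exact <- function(doses) {
  d <- sort(unique(doses))
  v <- vapply(d, function(x) mean(doses >= x), numeric(1))
  tibble::tibble(dose = d, volume = v)
}

# independent brute-force oracle for the MADD: volume-weighted mean |D - A|
voxel_madd_oracle <- function(doses, reference) mean(abs(doses - reference))

# small paired-score table with a planted number of gains
planted_pairs <- function(n, n_gain) {
  supine <- seq(1.5, 4, length.out = n)
  delta <- c(-runif(n_gain, 0.1, 1), runif(n - n_gain, 0, 1))
  tibble::tibble(patient_id = sprintf("P%03d", 1:n),
                 supine = supine, prone = supine + delta, delta = delta)
}

# analysis table from a direct-link synthetic cohort (characteristics + delta)
direct_analysis <- function(n = 200, seed = 1, ...) {
  co <- generate_cohort(cohort_config(n_patients = n, seed = seed,
                                      link_mode = "direct", ...))
  pairs <- pair_scores(co$scores)
  dplyr::inner_join(
    co$characteristics,
    dplyr::rename(pairs, supine_score = supine, prone_score = prone,
                  delta_penalty = delta),
    by = "patient_id")
}
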