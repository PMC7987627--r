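builtin_matrix <- function() {
  sets <- c("type1", "heart", "lungs", "ptvs", "body")
  sapply(sets, function(s) {
    ws <- builtin_weights(s)
    stats::setNames(ws$weight, ws$structure)[
      c("heart", "lung_right", "lung_left", "tumor_bed",
        "breast_left", "breast_right", "body")]
  })
}

test_that("built-in priority weight sets carry the published values and sum to 1", {
  m <- builtin_matrix()
  expect_identical(unname(m[, "type1"]), c(.40, .16, .14, .11, .09, .10, 0))
  expect_identical(unname(m[, "heart"]), c(.65, .08, .07, .10, .05, .05, 0))
  expect_identical(unname(m[, "lungs"]), c(.20, .30, .35, .07, .04, .04, 0))
  expect_identical(unname(m[, "ptvs"]), c(.15, .08, .07, .35, .30, .05, 0))
  expect_identical(unname(m[, "body"]), c(.10, .15, .15, .08, .07, .15, .30))
  expect_true(all(abs(colSums(m) - 1) < 1e-9))
  # only the body priority weights the external contour
  expect_equal(sum(m["body", ] > 0), 1)
  expect_error(builtin_weights("nope"), class = "dosegain_error_lookup")
})

test_that("weight sets are validated on construction and on file load", {
  expect_error(weight_set(c(heart = .5, body = .4)),
               class = "dosegain_error_invalid_argument")
  expect_error(weight_set(c(heart = 1.2, body = -.2)),
               class = "dosegain_error_invalid_argument")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("name: custom_heart", "weights:", "  heart: 0.7", "  body: 0.3"),
             path)
  ws <- read_weight_set(path)
  expect_s3_class(ws, "dosegain_weight_set")
  expect_equal(attr(ws, "name"), "custom_heart")
  expect_equal(sum(ws$weight), 1)
})

test_that("penalty score is the weighted MADD average (dot-product oracle)", {
  structures <- c("heart", "lung_right", "lung_left", "tumor_bed",
                  "breast_left", "breast_right", "body")
  const <- stats::setNames(rep(3, 7), structures)
  expect_equal(penalty_score(const, "type1"), 3)
  one <- stats::setNames(c(1, rep(0, 6)), structures)
  expect_equal(penalty_score(one, "heart"), 0.65)

  set.seed(5)
  for (nm in c("type1", "heart", "lungs", "ptvs", "body")) {
    for (i in 1:5) {
      madds <- stats::setNames(runif(7, 0, 10), structures)
      ws <- builtin_weights(nm)
      oracle <- sum(stats::setNames(ws$weight, ws$structure)[structures] * madds)
      score <- penalty_score(madds, nm)
      expect_equal(score, oracle, tolerance = 1e-12)
      # convexity: between min and max of the weighted structures
      active <- ws$structure[ws$weight > 0]
      expect_gte(score, min(madds[active]) - 1e-12)
      expect_lte(score, max(madds[active]) + 1e-12)
      # linearity in the MADDs
      expect_equal(penalty_score(madds * 2.5, nm), 2.5 * score, tolerance = 1e-12)
    }
  }
})

test_that("missing weighted structures error unless renormalization is requested", {
  madds <- c(heart = 2, lung_right = 1, lung_left = 4, tumor_bed = 2,
             breast_left = 3)
  expect_error(penalty_score(madds, "type1"),
               class = "dosegain_error_missing_structure")
  expect_warning(score <- penalty_score(madds, "type1", renormalize_missing = TRUE),
                 "Renormalizing")
  w <- c(.40, .16, .14, .11, .09) / (1 - .10)
  expect_equal(score, sum(w * madds), tolerance = 1e-12)
})

test_that("cohort scoring composes the single-plan path and pairs setups", {
  co <- generate_cohort(cohort_config(n_patients = 10, seed = 3, n_voxels = 2000))
  scored <- score_cohort(co$dvh, "type1")
  expect_equal(nrow(scored), 20)
  expect_setequal(unique(scored$setup), c("prone", "supine"))

  # compositional oracle: recompute one plan by hand through madd + penalty_score
  one <- co$dvh[co$dvh$patient_id == "P004" & co$dvh$setup == "prone", ]
  refs <- default_references()
  madds <- sapply(unique(one$structure), function(s) {
    madd(one[one$structure == s, c("dose", "volume")],
         refs$reference[refs$structure == s])
  })
  manual <- penalty_score(madds, "type1")
  expect_equal(scored$score[scored$patient_id == "P004" & scored$setup == "prone"],
               manual, tolerance = 1e-12)

  # identical prone and supine DVHs give identical scores
  sym <- co$dvh[co$dvh$setup == "supine", ]
  sym_prone <- sym
  sym_prone$setup <- "prone"
  both <- rbind(sym, sym_prone)
  s2 <- score_cohort(both, "type1")
  wide <- tidyr::pivot_wider(s2[, c("patient_id", "setup", "score")],
                             names_from = "setup", values_from = "score")
  expect_equal(wide$prone, wide$supine)

  # a patient lacking one setup is excluded with a warning
  broken <- co$dvh[!(co$dvh$patient_id == "P001" & co$dvh$setup == "prone"), ]
  expect_warning(s3 <- score_cohort(broken, "type1"), "P001")
  expect_false("P001" %in% s3$patient_id)
  expect_equal(nrow(s3), 18)
})
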