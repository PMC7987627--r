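test_that("derived pendulousness and size features propagate missingness", {
  d <- tibble::tibble(
    breast_depth_prone = c(80, 60, NA),
    breast_depth_supine = c(40, 0, 50),
    breast_volume_left = c(490, 300, 500),
    weight = c(70, NA, 80)
  )
  out <- derive_features(d)
  expect_equal(out$depth_ratio, c(2, NA, NA))
  expect_equal(out$delta_depth, c(40, 60, NA))
  expect_equal(out$volume_per_weight, c(7, NA, 6.25))
})

test_that("dummy coding maps the reference to 0 and rejects unseen levels", {
  expect_equal(dummy_code(c("bionix", "varian", "bionix"), "bionix"),
               c(0, 1, 0))
  expect_equal(dummy_code(rep("bionix", 4), "bionix",
                          levels = c("bionix", "varian")), rep(0, 4))
  expect_equal(dummy_code(c("lower_inner", "other", NA), "other"), c(1, 0, NA))
  expect_error(dummy_code(c("bionix", "siemens"), "bionix",
                          levels = c("bionix", "varian")),
               class = "dosegain_error_coding")
})

test_that("robust fit is exact on noiseless lines and agrees with OLS there", {
  d <- tibble::tibble(x = seq(0.5, 6, length.out = 25),
                      delta_penalty = 2 - 0.5 * seq(0.5, 6, length.out = 25))
  ft <- robust_fit(d, x)
  expect_equal(ft$intercept, 2, tolerance = 1e-8)
  expect_equal(ft$coefficient, -0.5, tolerance = 1e-8)
  ols <- stats::lm(delta_penalty ~ x, data = d)
  expect_equal(ft$coefficient, unname(stats::coef(ols)[2]), tolerance = 1e-8)
  expect_true(ft$significant)

  expect_error(robust_fit(tibble::tibble(x = rep(1, 20),
                                         delta_penalty = rnorm(20)), x),
               class = "dosegain_error_rank_deficient")
  expect_error(robust_fit(d[1:5, ], x),
               class = "dosegain_error_insufficient_data")
})

test_that("Huber fit shrugs off gross outliers that bias least squares", {
  set.seed(31)
  x <- runif(100, 0, 4)
  y <- 1 - x + rnorm(100, 0, 0.1)
  y[1:10] <- y[1:10] + 8
  d <- tibble::tibble(x = x, delta_penalty = y)
  ft <- robust_fit(d, x)
  expect_lt(abs(ft$coefficient - (-1)), 3 * ft$coefficient_sd)
  ols <- stats::lm(y ~ x)
  expect_gt(abs(unname(stats::coef(ols)[2]) - (-1)), 3 * ft$coefficient_sd)

  # a handful of extreme cases, as seen clinically: excluding them does not
  # remarkably change the robust line (slope moves by less than 1 SE)
  y3 <- 1 - x + rnorm(100, 0, 0.1)
  y3[1:3] <- y3[1:3] + 8
  d3 <- tibble::tibble(x = x, delta_penalty = y3)
  ft3 <- robust_fit(d3, x)
  ft3_clean <- robust_fit(d3[-(1:3), ], x)
  expect_lt(abs(ft3_clean$coefficient - ft3$coefficient), ft3$coefficient_sd)
})

test_that("cutoff extraction inverts the fitted line with direction and NI rules", {
  co <- extract_cutoff(0.278, -0.0073)
  expect_equal(format_cutoff(co$cutoff, "mm"), 38)
  expect_equal(co$direction, "greater_better")

  co <- extract_cutoff(-0.640, 0.0970)
  expect_equal(format_cutoff(co$cutoff, "L"), 6.6)
  expect_equal(co$direction, "less_better")

  expect_equal(extract_cutoff(0, -0.5)$cutoff, 0)
  # near-zero slope -> not identifiable
  expect_false(extract_cutoff(0.1, 0.004, coefficient_sd = 0.01)$identifiable)
  # crossing outside the plausible range -> not identifiable
  expect_false(extract_cutoff(-0.124, -0.2865, x_range = c(0, 1))$identifiable)
  expect_false(extract_cutoff(0.1, 0)$identifiable)

  # the fitted difference is zero at the cutoff and favours prone beyond it
  ft <- robust_fit(tibble::tibble(x = seq(1, 5, length.out = 30),
                                  delta_penalty = 1.5 - 0.6 * seq(1, 5, length.out = 30)),
                   x)
  co <- cutoff_from_fit(ft)
  expect_equal(ft$intercept + ft$coefficient * co$cutoff, 0, tolerance = 1e-9)
  expect_lt(ft$intercept + ft$coefficient * (co$cutoff + 0.5), 0)
})

test_that("FP1 selection keeps straight lines, finds the log, shifts x <= 0", {
  set.seed(33)
  x <- runif(200, 1, 5)
  lin <- tibble::tibble(x = x, delta_penalty = 1 - 0.5 * x + rnorm(200, 0, 0.2))
  expect_equal(fp_select(lin, x)$form, "linear")

  xl <- exp(rnorm(200, 1, 0.6))
  lg <- tibble::tibble(x = xl, delta_penalty = log(xl) + rnorm(200, 0, 0.15))
  sel <- fp_select(lg, x)
  expect_equal(sel$form, "fp1")
  expect_equal(sel$power, 0)

  # non-positive predictor is shifted, not rejected
  sh <- tibble::tibble(x = x - 2, delta_penalty = lin$delta_penalty)
  out <- fp_select(sh, x)
  expect_gt(out$shift, 0)
  expect_true(out$form %in% c("linear", "fp1"))

  td <- tidy(sel)
  expect_equal(td$form, "fp1")
  expect_lt(td$p_linear_vs_fp1, 0.05)
})

test_that("screening recovers a planted depth-ratio signal and ranks deterministically", {
  a <- direct_analysis(n = 200, seed = 14)
  suppressWarnings(scr <- screen_all(a, fp = FALSE))
  ratio_row <- scr[scr$characteristic == "Breast depth ratio prone/supine", ]
  couch_row <- scr[scr$characteristic == "Couch type Varian vs Bionix", ]
  expect_true(ratio_row$significant)
  expect_lt(ratio_row$coefficient, 0)
  expect_equal(ratio_row$direction, "greater_better")
  expect_false(couch_row$significant)
  # post-dosimetry: higher supine penalty predicts a prone gain
  sup_row <- scr[scr$characteristic == "Supine penalty score", ]
  expect_lt(sup_row$coefficient, 0)

  # deterministic output and ordering across runs
  suppressWarnings(scr2 <- screen_all(a, fp = FALSE))
  expect_identical(scr, scr2)
  expect_equal(scr$group[1], "Pendulousness")

  expect_error(screen_all(dplyr::select(a, -delta_penalty)),
               class = "dosegain_error_invalid_argument")
})

test_that("tidy and glance expose the fit in broom form", {
  d <- tibble::tibble(x = seq(1, 4, length.out = 40),
                      delta_penalty = 1 - 0.4 * seq(1, 4, length.out = 40) +
                        stats::rnorm(40, 0, 0.05))
  ft <- robust_fit(d, x)
  td <- tidy(ft)
  expect_equal(td$term, c("(Intercept)", "x"))
  expect_equal(td$estimate[2], ft$coefficient)
  gl <- glance(ft)
  expect_equal(gl$n, 40)
  expect_true(gl$converged)
  p <- ggplot2::autoplot(ft)
  expect_s3_class(p, "ggplot")
})
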