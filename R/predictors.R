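# Univariable screening of patient characteristics against the penalty
# difference delta = prone - supine.
#
# Each characteristic is fit alone by Huber robust linear regression
# (MASS::rlm, M-estimation, tuning constant 1.345, MAD scale); a
# fractional-polynomial check with one power term flags characteristics
# whose relation to delta is convincingly nonlinear. The fitted line's zero
# crossing, -intercept/coefficient, is the cutoff where the predicted gain
# changes sign.

#' Derive pendulousness and size features from raw characteristics
#'
#' Adds `depth_ratio` (prone/supine breast depth), `delta_depth`
#' (prone - supine depth, mm) and `volume_per_weight` (ipsilateral breast
#' volume over body weight, mL/kg). A feature is left missing whenever an
#' input is missing or a supine depth is zero.
#'
#' @param data Characteristics table with (any of) `breast_depth_prone`,
#'   `breast_depth_supine` (mm), `breast_volume_left` (mL), `weight` (kg).
#'
#' @return `data` with the derived columns appended.
#' @export
derive_features <- function(data) {
  get0c <- function(nm) {
    if (nm %in% names(data)) data[[nm]] else rep(NA_real_, nrow(data))
  }
  dp <- get0c("breast_depth_prone")
  ds <- get0c("breast_depth_supine")
  bv <- get0c("breast_volume_left")
  wt <- get0c("weight")
  ds_safe <- ifelse(!is.na(ds) & ds > 0, ds, NA_real_)
  wt_safe <- ifelse(!is.na(wt) & wt > 0, wt, NA_real_)
  dplyr::mutate(
    tibble::as_tibble(data),
    depth_ratio = dp / ds_safe,
    delta_depth = dp - ds,
    volume_per_weight = bv / wt_safe
  )
}

#' Dummy-code a categorical characteristic against a reference level
#'
#' Binary 0/1 coding: the reference level maps to 0, every other declared
#' level to 1, so the regression coefficient is the change in the response
#' between the reference and the rest.
#'
#' @param x Character or factor vector.
#' @param reference The reference level (coded 0).
#' @param levels Declared level set; defaults to the levels observed in `x`
#'   plus `reference`. Values outside it are a coding error.
#'
#' @return Numeric 0/1 vector with `NA` preserved.
#' @export
dummy_code <- function(x, reference, levels = NULL) {
  x <- as.character(x)
  lev <- levels %||% unique(c(reference, x[!is.na(x)]))
  if (!reference %in% lev) {
    rlang::abort("`reference` is not among the declared levels.",
                 class = "dosegain_error_coding")
  }
  unseen <- setdiff(unique(x[!is.na(x)]), lev)
  if (length(unseen) > 0) {
    rlang::abort(paste0("Level(s) not in the declared set: ",
                        paste(unseen, collapse = ", ")),
                 class = "dosegain_error_coding")
  }
  ifelse(is.na(x), NA_real_, as.numeric(x != reference))
}

#' Huber robust linear fit of one characteristic
#'
#' Univariable M-estimated regression `y ~ x` via [MASS::rlm()] with the
#' Huber psi (tuning constant 1.345), scale from the median absolute
#' deviation, iteratively reweighted least squares (up to 50 iterations,
#' coefficient convergence 1e-8). A coefficient is flagged significant when
#' `|coefficient / SE| > 1.96`. Complete cases only.
#'
#' @param data Data frame holding the two variables.
#' @param x,y Column names (tidy-eval) of the characteristic and the
#'   response; `y` defaults to `delta_penalty`.
#' @param characteristic Label for reports; defaults to the `x` column name.
#' @param min_n Minimum number of complete cases (default 10).
#'
#' @return A `gain_fit` object: list with `characteristic`, `n`,
#'   `intercept`, `coefficient`, `coefficient_sd`, `significant`, `x_range`,
#'   and the underlying `rlm` fit. Has [tidy()][generics::tidy] and
#'   [glance()][generics::glance] methods.
#' @export
#'
#' @examples
#' d <- data.frame(ratio = 1:20 / 5, delta_penalty = 2 - 0.5 * (1:20 / 5))
#' robust_fit(d, ratio)
robust_fit <- function(data, x, y = delta_penalty, characteristic = NULL,
                       min_n = 10) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  characteristic <- characteristic %||% rlang::as_name(rlang::enquo(x))
  ok <- stats::complete.cases(xv, yv)
  xv <- as.numeric(xv[ok])
  yv <- as.numeric(yv[ok])
  if (length(xv) < min_n) {
    rlang::abort(sprintf("Only %d complete cases for '%s' (need >= %d).",
                         length(xv), characteristic, min_n),
                 class = "dosegain_error_insufficient_data")
  }
  if (stats::sd(xv) == 0) {
    rlang::abort(sprintf("Characteristic '%s' is constant; fit is rank-deficient.",
                         characteristic),
                 class = "dosegain_error_rank_deficient")
  }
  # an exact linear relation makes the MAD scale collapse and IRLS cycle;
  # there the M-estimate coincides with least squares, so use it directly
  ls <- stats::lm(yv ~ xv)
  perfect <- sqrt(mean(ls$residuals^2)) < 1e-10 * (stats::sd(yv) + 1e-30)
  fit <- if (perfect) {
    ls
  } else {
    MASS::rlm(yv ~ xv, psi = MASS::psi.huber, k = 1.345,
              scale.est = "MAD", maxit = 50, acc = 1e-8)
  }
  cf <- stats::coef(fit)
  se <- if (perfect) {
    suppressWarnings(sqrt(diag(stats::vcov(fit)))) # zero-residual summary
  } else {
    sqrt(diag(stats::vcov(fit)))
  }
  out <- list(
    characteristic = characteristic,
    n = length(xv),
    intercept = unname(cf[1]),
    coefficient = unname(cf[2]),
    coefficient_sd = unname(se[2]),
    intercept_sd = unname(se[1]),
    significant = abs(cf[2] / se[2]) > 1.96,
    x_range = range(xv),
    fit = fit
  )
  class(out) <- "gain_fit"
  out
}

#' @export
print.gain_fit <- function(x, ...) {
  cat(sprintf("<gain_fit> %s (n = %d)\n", x$characteristic, x$n))
  cat(sprintf("  delta = %.4f %+.4f * x   (SE %.4f)%s\n",
              x$intercept, x$coefficient, x$coefficient_sd,
              if (isTRUE(x$significant)) "  *" else ""))
  co <- cutoff_from_fit(x)
  if (is.na(co$cutoff)) {
    cat("  cutoff: not identifiable\n")
  } else {
    cat(sprintf("  prone better when x %s %.4g\n",
                if (co$direction == "greater_better") ">" else "<", co$cutoff))
  }
  invisible(x)
}

#' Zero-crossing cutoff of a fitted gain line
#'
#' The fitted penalty difference `delta(x) = intercept + coefficient * x`
#' changes sign at `x = -intercept / coefficient`. When the coefficient is
#' negative, larger values of the characteristic favour prone
#' (`greater_better`); when positive, smaller values do (`less_better`). The
#' cutoff is declared not identifiable when the coefficient is
#' indistinguishable from zero (`|coefficient/SD| < 0.5`) or the crossing
#' lies outside the plausible range of the characteristic.
#'
#' @param object A `gain_fit` from [robust_fit()].
#' @param x_range Optional length-2 plausible range overriding the observed
#'   one.
#'
#' @return A one-row tibble `cutoff, direction, identifiable`; `cutoff` is
#'   `NA` when not identifiable.
#' @export
cutoff_from_fit <- function(object, x_range = NULL) {
  extract_cutoff(object$intercept, object$coefficient,
                 coefficient_sd = object$coefficient_sd,
                 x_range = x_range %||% object$x_range)
}

#' Cutoff from explicit regression estimates
#'
#' Same rule as [cutoff_from_fit()] but from bare numbers, e.g. previously
#' reported intercept/coefficient pairs.
#'
#' @param intercept,coefficient Fitted line parameters.
#' @param coefficient_sd Optional coefficient standard error for the
#'   near-zero-slope rule.
#' @param x_range Optional plausible range of the characteristic.
#'
#' @return A one-row tibble `cutoff, direction, identifiable`.
#' @export
#'
#' @examples
#' extract_cutoff(0.278, -0.0073)   # prone better above 38 (mm)
extract_cutoff <- function(intercept, coefficient, coefficient_sd = NULL,
                           x_range = NULL) {
  ni <- tibble::tibble(cutoff = NA_real_, direction = NA_character_,
                       identifiable = FALSE)
  if (!is.finite(coefficient) || coefficient == 0) return(ni)
  if (!is.null(coefficient_sd) && is.finite(coefficient_sd) &&
      abs(coefficient / coefficient_sd) < 0.5) {
    return(ni)
  }
  cutoff <- -intercept / coefficient
  if (!is.null(x_range) && (cutoff < min(x_range) || cutoff > max(x_range))) {
    return(ni)
  }
  tibble::tibble(
    cutoff = cutoff,
    direction = if (coefficient < 0) "greater_better" else "less_better",
    identifiable = TRUE
  )
}

fp_powers_default <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

fp_transform <- function(x, power) {
  if (power == 0) log(x) else x^power
}

#' Fractional-polynomial (FP1) nonlinearity check
#'
#' Selects among a null model, a straight line and a one-power fractional
#' polynomial `y ~ x^p` with `p` from \{-2, -1, -0.5, 0 (log), 0.5, 1, 2,
#' 3\}, by a closed test on Gaussian deviance: first the best FP1 against
#' the null on 2 degrees of freedom (one for the power choice, one for the
#' slope), then the best FP1 against the straight line on 1 degree of
#' freedom. Non-positive predictors are shifted by the standard rule
#' (minus the minimum plus the smallest gap between distinct values) before
#' transforming.
#'
#' @param data Data frame holding the two variables.
#' @param x,y Column names (tidy-eval); `y` defaults to `delta_penalty`.
#' @param alpha Test level of the closed test (default 0.05).
#' @param powers Candidate FP1 powers.
#'
#' @return A list of class `fp_select`: `form` in
#'   `{"null", "linear", "fp1"}`, selected `power`, applied `shift`,
#'   deviances per power, and the two closed-test p-values
#'   (`p_null_vs_fp1`, `p_linear_vs_fp1`).
#' @export
fp_select <- function(data, x, y = delta_penalty, alpha = 0.05,
                      powers = fp_powers_default) {
  xv <- as.numeric(dplyr::pull(data, {{ x }}))
  yv <- as.numeric(dplyr::pull(data, {{ y }}))
  ok <- stats::complete.cases(xv, yv)
  xv <- xv[ok]
  yv <- yv[ok]
  n <- length(xv)
  if (n < 10 || stats::sd(xv) == 0) {
    rlang::abort("Need >= 10 complete cases with a non-constant predictor.",
                 class = "dosegain_error_insufficient_data")
  }
  shift <- 0
  if (min(xv) <= 0) {
    ux <- sort(unique(xv))
    if (length(ux) < 2) {
      rlang::abort("Cannot shift a constant non-positive predictor.",
                   class = "dosegain_error_transform")
    }
    shift <- -min(xv) + min(diff(ux))
  }
  xs <- xv + shift
  rss <- function(pred) {
    f <- stats::lm.fit(cbind(1, pred), yv)
    sum(f$residuals^2)
  }
  dev <- function(r) n * log(r / n)
  rss_null <- sum((yv - mean(yv))^2)
  rss_p <- vapply(powers, function(p) rss(fp_transform(xs, p)), numeric(1))
  dev_null <- dev(rss_null)
  dev_p <- dev(rss_p)
  best <- which.min(dev_p)
  if (!1 %in% powers) {
    rlang::abort("`powers` must include 1 (the straight line).",
                 class = "dosegain_error_invalid_argument")
  }
  dev_lin <- dev_p[powers == 1]
  p_null <- stats::pchisq(dev_null - dev_p[best], df = 2, lower.tail = FALSE)
  p_lin <- stats::pchisq(dev_lin - dev_p[best], df = 1, lower.tail = FALSE)
  form <- if (p_null > alpha) {
    "null"
  } else if (p_lin > alpha || powers[best] == 1) {
    "linear"
  } else {
    "fp1"
  }
  structure(list(
    form = form,
    power = if (form == "fp1") powers[best] else if (form == "linear") 1 else NA_real_,
    best_power = powers[best],
    shift = shift,
    n = n,
    deviances = stats::setNames(dev_p, paste0("p", powers)),
    deviance_null = dev_null,
    p_null_vs_fp1 = p_null,
    p_linear_vs_fp1 = p_lin,
    alpha = alpha
  ), class = "fp_select")
}

#' @export
print.fp_select <- function(x, ...) {
  cat(sprintf("<fp_select> form = %s", x$form))
  if (x$form == "fp1") cat(sprintf(" (power %g)", x$power))
  cat(sprintf("; n = %d, shift = %g\n", x$n, x$shift))
  cat(sprintf("  null vs best FP1 (2 df): p = %.4g\n", x$p_null_vs_fp1))
  cat(sprintf("  linear vs best FP1 (1 df): p = %.4g\n", x$p_linear_vs_fp1))
  invisible(x)
}

# Screening plan: one row per characteristic in report order.
screening_plan <- function() {
  tibble::tribble(
    ~group, ~characteristic, ~column, ~unit, ~digits,
    "Pendulousness", "Breast depth ratio prone/supine", "depth_ratio", "ratio", 1,
    "Pendulousness", "Breast depth difference prone-supine", "delta_depth", "mm", 0,
    "Pendulousness", "Breast depth prone", "breast_depth_prone", "mm", 0,
    "Breast/body", "Breast volume/body weight ratio", "volume_per_weight", "mL/kg", 1,
    "Tumor location", "Lower inner quadrant vs not", ".liq", "binary", NA,
    "Breast size", "Left breast volume supine", "breast_volume_left", "mL", 0,
    "Breast size", "Right breast volume supine", "breast_volume_right", "mL", 0,
    "Breast size", "Breast depth supine", "breast_depth_supine", "mm", 0,
    "Body size", "Weight", "weight", "kg", 0,
    "Body size", "Body mass index", "bmi", "kg/m2", 0,
    "Body size", "Heart volume supine", "heart_volume", "mL", 0,
    "Body size", "Height", "height", "cm", 0,
    "DiBH capability", "Right lung volume supine", "lung_volume_right", "L", 1,
    "DiBH capability", "Total lung volume supine", "lung_volume_total", "L", 1,
    "DiBH capability", "Left lung volume supine", "lung_volume_left", "L", 1,
    "DiBH capability", "Age", "age", "years", 0,
    "DiBH capability", "LAD-chest wall distance", "lad_chest_distance", "mm", 0,
    "Other", "Couch type Varian vs Bionix", ".couch_varian", "binary", NA,
    "Other", "Preference prone vs else", ".pref_prone", "binary", NA,
    "Post-dosimetry", "Prone penalty score", "prone_score", "%dose", 1,
    "Post-dosimetry", "Supine penalty score", "supine_score", "%dose", 1
  )
}

#' Univariable screening of all characteristics
#'
#' Runs [robust_fit()] for every available characteristic against the
#' penalty difference, in a fixed report order grouped by clinical theme
#' (pendulousness, breast/body, tumor location, breast size, body size,
#' breath-hold capability, other, then the post-dosimetry penalty scores
#' themselves). Categorical characteristics are dummy-coded; derived
#' features are computed with [derive_features()] if absent. Optionally
#' attaches the FP1 nonlinearity verdict per characteristic.
#'
#' @param data Characteristics table including `delta_penalty` and, for the
#'   post-dosimetry rows, `supine_score` and `prone_score`.
#' @param alpha Level of the FP closed test.
#' @param fp Run the nonlinearity check per characteristic (default TRUE).
#' @param min_n Minimum complete cases per characteristic.
#' @param exclude Patient ids to drop before fitting (e.g. known outliers).
#'
#' @return A tibble with one row per characteristic: `group`,
#'   `characteristic`, `n`, `intercept`, `coefficient`, `coefficient_sd`,
#'   `significant`, `nonlinear` (if `fp`), `fp_power`, `cutoff`,
#'   `direction`, `unit`. Characteristics without enough data are skipped
#'   with a warning.
#' @export
screen_all <- function(data, alpha = 0.05, fp = TRUE, min_n = 10,
                       exclude = NULL) {
  if (!"delta_penalty" %in% names(data)) {
    rlang::abort("`data` must contain `delta_penalty` (prone - supine score).",
                 class = "dosegain_error_invalid_argument")
  }
  if (!is.null(exclude) && "patient_id" %in% names(data)) {
    data <- dplyr::filter(data, !.data$patient_id %in% exclude)
  }
  data <- derive_features(data)
  if ("tumor_location" %in% names(data)) {
    data$.liq <- dummy_code(ifelse(data$tumor_location == "lower_inner",
                                   "lower_inner", "other"), reference = "other")
  }
  if ("couch" %in% names(data)) {
    data$.couch_varian <- dummy_code(data$couch, reference = "bionix",
                                     levels = c("bionix", "varian"))
  }
  if ("preference" %in% names(data)) {
    data$.pref_prone <- dummy_code(ifelse(data$preference == "prone",
                                          "prone", "else"), reference = "else")
  }
  plan <- screening_plan()
  rows <- purrr::pmap(plan, function(group, characteristic, column, unit, digits) {
    if (!column %in% names(data) || all(is.na(data[[column]]))) {
      rlang::warn(paste0("Skipping '", characteristic, "': no data."))
      return(NULL)
    }
    ft <- tryCatch(
      robust_fit(data, !!rlang::sym(column), characteristic = characteristic,
                 min_n = min_n),
      dosegain_error_insufficient_data = function(e) {
        rlang::warn(paste0("Skipping '", characteristic, "': ",
                           conditionMessage(e)))
        NULL
      },
      dosegain_error_rank_deficient = function(e) {
        rlang::warn(paste0("Skipping '", characteristic, "': ",
                           conditionMessage(e)))
        NULL
      }
    )
    if (is.null(ft)) return(NULL)
    co <- cutoff_from_fit(ft)
    nl <- NA
    pw <- NA_real_
    if (fp && unit != "binary") {
      sel <- tryCatch(
        fp_select(data, !!rlang::sym(column), alpha = alpha),
        dosegain_error_insufficient_data = function(e) NULL,
        dosegain_error_transform = function(e) NULL
      )
      if (!is.null(sel)) {
        nl <- sel$form == "fp1"
        pw <- if (isTRUE(nl)) sel$power else NA_real_
      }
    }
    tibble::tibble(
      group = group, characteristic = characteristic, n = ft$n,
      intercept = ft$intercept, coefficient = ft$coefficient,
      coefficient_sd = ft$coefficient_sd,
      significant = unname(ft$significant),
      nonlinear = nl, fp_power = pw,
      cutoff = co$cutoff, direction = co$direction, unit = unit
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!fp) out <- dplyr::select(out, -"nonlinear", -"fp_power")
  out
}

#' Round a cutoff to its report precision
#'
#' Integer precision for lengths, volumes, masses, ages and heights; one
#' decimal for ratios, litres and percent-dose values. Rounds half away
#' from zero, matching clinical table conventions.
#'
#' @param cutoff Numeric cutoffs.
#' @param unit Matching units (`"mm"`, `"mL"`, `"kg"`, `"kg/m2"`, `"cm"`,
#'   `"years"`, `"ratio"`, `"L"`, `"mL/kg"`, `"%dose"`).
#'
#' @return Rounded cutoffs.
#' @export
format_cutoff <- function(cutoff, unit) {
  digits <- ifelse(unit %in% c("ratio", "L", "mL/kg", "%dose"), 1, 0)
  round_half_up(cutoff, digits)
}
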