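# broom-style accessors for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a robust gain fit
#'
#' @param x A `gain_fit` from [robust_fit()].
#' @param ... Ignored.
#'
#' @return A tibble with one row per term: `term`, `estimate`, `std.error`,
#'   `statistic`.
#' @method tidy gain_fit
#' @export
tidy.gain_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", x$characteristic),
    estimate = c(x$intercept, x$coefficient),
    std.error = c(x$intercept_sd, x$coefficient_sd),
    statistic = c(x$intercept, x$coefficient) / c(x$intercept_sd, x$coefficient_sd)
  )
}

#' Glance at a robust gain fit
#'
#' @param x A `gain_fit` from [robust_fit()].
#' @param ... Ignored.
#'
#' @return A one-row tibble: `n`, `sigma` (robust scale), `converged`,
#'   `significant`, `cutoff`, `direction`.
#' @method glance gain_fit
#' @export
glance.gain_fit <- function(x, ...) {
  co <- cutoff_from_fit(x)
  tibble::tibble(
    n = x$n, sigma = x$fit$s %||% stats::sigma(x$fit),
    converged = x$fit$converged %||% TRUE,
    significant = unname(x$significant),
    cutoff = co$cutoff, direction = co$direction
  )
}

#' Tidy a fractional-polynomial selection
#'
#' @param x An `fp_select` object.
#' @param ... Ignored.
#'
#' @return A one-row tibble: `form`, `power`, `p_null_vs_fp1`,
#'   `p_linear_vs_fp1`, `n`, `shift`.
#' @method tidy fp_select
#' @export
tidy.fp_select <- function(x, ...) {
  tibble::tibble(form = x$form, power = x$power,
                 p_null_vs_fp1 = x$p_null_vs_fp1,
                 p_linear_vs_fp1 = x$p_linear_vs_fp1,
                 n = x$n, shift = x$shift)
}
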