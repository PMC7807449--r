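# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname arrhenius
#' @param x An `arrhenius_fit`.
#' @param ... Unused.
#' @export
tidy.arrhenius_fit <- function(x, ...) {
  tibble::tibble(
    term = c("Ea", "lnA"),
    estimate = c(x$Ea, x$lnA),
    std.error = c(x$se_Ea, x$se_lnA),
    unit = c("kcal/mol", "ln(rate)")
  )
}

#' @rdname arrhenius
#' @export
glance.arrhenius_fit <- function(x, ...) {
  tibble::tibble(
    Ea = x$Ea, se_Ea = x$se_Ea, lnA = x$lnA,
    r.squared = x$r_squared, nobs = nrow(x$data),
    n_excluded = if (is.null(x$excluded)) 0L else nrow(x$excluded)
  )
}

#' @rdname fit_vs_temperature
#' @param x A `temperature_fit`.
#' @param ... Unused.
#' @export
tidy.temperature_fit <- function(x, ...) {
  cf <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = cf[, 2]
  )
}

#' @rdname fit_vs_temperature
#' @export
glance.temperature_fit <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, intercept = x$intercept,
    r.squared = x$r_squared, nobs = nrow(x$data),
    n_excluded = nrow(x$excluded)
  )
}
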