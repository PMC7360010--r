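#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @exportS3Method generics::tidy
tidy.line_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = c(x$se_intercept, x$se_slope)
  )
}

#' @exportS3Method generics::glance
glance.line_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    r.squared = s$r.squared, sigma = x$sigma, nobs = x$n,
    df.residual = x$fit$df.residual
  )
}

#' @exportS3Method generics::tidy
tidy.detection_curve <- function(x, ...) {
  tibble::tibble(
    term = c("beta0", "beta1"),
    estimate = c(x$beta0, x$beta1),
    std.error = sqrt(diag(x$vcov))
  )
}

#' @exportS3Method generics::glance
glance.detection_curve <- function(x, ...) {
  tibble::tibble(
    nobs = x$n, separation = x$separation,
    x50 = -x$beta0 / x$beta1
  )
}

#' @exportS3Method generics::tidy
tidy.lld_result <- function(x, ...) {
  tibble::tibble(
    rule = x$rule,
    cnr_threshold = x$cnr_threshold,
    lld_cells = x$lld_cells,
    lld_specific_activity = x$lld_specific_activity,
    n = x$n
  )
}

#' @exportS3Method generics::tidy
tidy.rc_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(term = c("slope", "intercept"),
                   estimate = c(x$slope, x$intercept), group = "fixed"),
    tibble::tibble(term = names(x$ranef), estimate = unname(x$ranef),
                   group = "scanner")
  )
}

#' @exportS3Method generics::glance
glance.rc_fit <- function(x, ...) {
  tibble::tibble(sigma = x$sigma, nobs = x$n, method = x$method)
}
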