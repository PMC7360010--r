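#' Plot a fitted detection-probability curve
#'
#' Shows the logistic detection-probability curve on a log cell-number axis
#' with the underlying binary detection outcomes.
#'
#' @param object A [fit_logistic()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.detection_curve <- function(object, ...) {
  d <- object$data
  rng <- range(d$cell_number[d$cell_number > 0])
  grid <- tibble::tibble(
    cell_number = exp(seq(log(rng[1]), log(rng[2]), length.out = 200))
  )
  grid$p <- detection_probability(object, grid$cell_number)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cell_number)) +
    ggplot2::geom_point(ggplot2::aes(y = as.numeric(.data$detected)),
                        alpha = 0.4, shape = 16) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$p), linewidth = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "Cell number", y = "Detection probability",
      title = "Logistic detection-probability curve"
    )
}

#' Plot the recovery-coefficient model fit
#'
#' Recovery coefficient against `ln(CD * SA)` with the population fit line
#' (and per-scanner lines when random intercepts were estimated).
#'
#' @param object An [rc_fit] from [fit_rc_model()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.rc_fit <- function(object, ...) {
  if (is.null(object$data)) {
    stop("this rc_fit carries no data (constructed from coefficients)",
      call. = FALSE
    )
  }
  d <- object$data
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$rc,
                                       colour = .data$scanner)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         linewidth = 0.8) +
    ggplot2::labs(
      x = "ln(cell density x specific activity)  [ln(kBq/mL)]",
      y = "Recovery coefficient",
      title = "Recovery coefficient vs. activity concentration"
    )
  for (s in names(object$ranef)) {
    p <- p + ggplot2::geom_abline(
      intercept = object$intercept + object$ranef[[s]],
      slope = object$slope, linetype = "dashed", alpha = 0.6
    )
  }
  p
}

#' Plot the 90%-detection cell number against background level
#'
#' @param object A [detection_vs_background()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.background_detection <- function(object, ...) {
  d <- dplyr::filter(tibble::as_tibble(object), !.data$inestimable)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fraction, y = .data$cells_at_p)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "Background fraction of well concentration",
      y = sprintf("Cells for %d%% detection probability",
                  round(100 * attr(object, "p"))),
      title = "Detection limit vs. non-specific background"
    )
}

#' Bland-Altman plot
#'
#' Pairwise differences against pairwise means with the bias and 95% limits
#' of agreement.
#'
#' @param object A [bland_altman()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.agreement <- function(object, ...) {
  pairs <- attr(object, "pairs")
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$bias, linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(
      x = "Mean of paired measurements", y = "Difference",
      title = "Bland-Altman agreement"
    )
}
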