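#' Physical half-life of zirconium-89, in hours
#'
#' @export
ZR89_HALF_LIFE_H <- 78.4

#' Radioactive decay factor
#'
#' Fraction of activity remaining after `elapsed` hours:
#' `2^(-elapsed / half_life)`. Negative elapsed times back-correct. The
#' factor is multiplicative over consecutive intervals.
#'
#' @param elapsed Elapsed time in hours (vectorized; negative allowed).
#' @param half_life Isotope half-life in hours (default: zirconium-89,
#'   78.4 h).
#' @return Fraction of activity remaining.
#' @export
#' @examples
#' decay_factor(78.4) # 0.5
decay_factor <- function(elapsed, half_life = ZR89_HALF_LIFE_H) {
  if (any(!is.finite(elapsed))) stop("elapsed must be finite", call. = FALSE)
  if (half_life <= 0) stop("half_life must be positive", call. = FALSE)
  2^(-elapsed / half_life)
}

#' Decay-correct an activity to a reference time
#'
#' Converts an activity measured at `t_measured` to its value at
#' `t_reference`: `activity / decay_factor(t_measured - t_reference)`.
#' Round-trips exactly with [decay_factor()].
#'
#' @param activity Measured activity, kBq.
#' @param t_measured,t_reference Time points in hours (any common origin).
#' @param half_life Isotope half-life in hours.
#' @return Activity at the reference time, kBq.
#' @export
#' @examples
#' decay_correct(5, t_measured = 78.4, t_reference = 0) # 10
decay_correct <- function(activity, t_measured, t_reference,
                          half_life = ZR89_HALF_LIFE_H) {
  if (any(!is.finite(t_measured)) || any(!is.finite(t_reference))) {
    stop("timestamps must be finite", call. = FALSE)
  }
  activity / decay_factor(t_measured - t_reference, half_life)
}

#' Pearson correlation between two columns
#'
#' Product-moment correlation with a two-sided t-test p-value, via
#' [stats::cor.test()].
#'
#' @param data A data frame.
#' @param x,y Unquoted numeric columns.
#' @return A tibble with `r`, `p_value`, `n`.
#' @export
pearson <- function(data, x, y) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    stop("constant input: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(xv, yv, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(xv))
}

#' Bland-Altman agreement analysis
#'
#' Computes the differences `a - b`, their mean (bias) and the 95% limits of
#' agreement `bias +/- 1.96 * SD(differences)`.
#'
#' @param data A data frame of paired measurements.
#' @param a,b Unquoted numeric columns (e.g. the two scanners).
#' @return A tibble of class `agreement` with `bias`, `loa_low`, `loa_high`,
#'   `sd_diff`, `n`; the per-pair means and differences are attached as
#'   attribute `"pairs"` for plotting.
#' @export
bland_altman <- function(data, a, b) {
  av <- dplyr::pull(data, {{ a }})
  bv <- dplyr::pull(data, {{ b }})
  if (length(av) != length(bv)) stop("inputs must have equal length", call. = FALSE)
  ok <- is.finite(av) & is.finite(bv)
  av <- av[ok]; bv <- bv[ok]
  if (length(av) < 2L) stop("need at least 2 complete pairs", call. = FALSE)
  d <- av - bv
  s <- stats::sd(d)
  out <- tibble::tibble(
    bias = mean(d),
    loa_low = mean(d) - 1.96 * s,
    loa_high = mean(d) + 1.96 * s,
    sd_diff = s,
    n = length(d)
  )
  class(out) <- c("agreement", class(out))
  attr(out, "pairs") <- tibble::tibble(mean = (av + bv) / 2, diff = d)
  out
}
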