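#' Ordinary least-squares line fit with mean-response confidence intervals
#'
#' Thin wrapper around [stats::lm()] exposing the pieces the
#' detection-limit calculation needs: slope, intercept, their standard
#' errors, the residual SD, and the two-sided 95% confidence interval of the
#' mean response at any predictor value (t distribution, n - 2 df).
#'
#' @param data A data frame.
#' @param x,y Unquoted predictor and response columns.
#' @return An object of class `line_fit`.
#' @export
#' @examples
#' d <- tibble::tibble(u = 1:5, v = 2 * (1:5) + 1)
#' fit_line(d, u, v)$slope # 2
fit_line <- function(data, x, y) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 3L) stop("need at least 3 points for a line fit", call. = FALSE)
  if (stats::sd(xv) == 0) stop("degenerate predictor (singular fit)", call. = FALSE)
  df <- data.frame(.x = xv, .y = yv)
  fit <- stats::lm(.y ~ .x, data = df)
  # exact linear data is a legitimate input here; silence the perfect-fit note
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  cf <- sm$coefficients
  structure(
    list(
      fit = fit,
      slope = unname(cf[".x", "Estimate"]),
      intercept = unname(cf["(Intercept)", "Estimate"]),
      se_slope = unname(cf[".x", "Std. Error"]),
      se_intercept = unname(cf["(Intercept)", "Std. Error"]),
      sigma = sm$sigma,
      n = length(xv)
    ),
    class = "line_fit"
  )
}

#' Confidence interval of the mean response of a line fit
#'
#' @param object A [fit_line()] result.
#' @param x0 Predictor value(s) at which to evaluate.
#' @param level Confidence level (default 0.95).
#' @return A tibble with `x`, `fit`, `lwr`, `upr`.
#' @export
ci_mean <- function(object, x0, level = 0.95) {
  stopifnot(inherits(object, "line_fit"))
  pr <- stats::predict(object$fit, newdata = data.frame(.x = x0),
                       interval = "confidence", level = level)
  tibble::tibble(x = x0, fit = pr[, "fit"], lwr = pr[, "lwr"], upr = pr[, "upr"])
}

#' Estimate the lower limit of detection from well CNR data
#'
#' Implements the regression-based LLD procedure: (1) regress CNR on
#' specific activity over all unexcluded wells; (2) take as the CNR
#' detection threshold either the upper bound of the two-sided 95%
#' confidence interval of the mean CNR at `lld_ci_at` (rule `"ci95_upper"`,
#' default at a specific activity of 0, i.e. the largest CNR plausibly seen
#' at vanishing label) or the Rose criterion value (rule `"rose"`,
#' `cnr_threshold = 5`); (3) invert the CNR-vs-cell-number regression at
#' that threshold to obtain the LLD in cells; (4) invert the
#' CNR-vs-specific-activity regression to obtain the specific activity at
#' the LLD.
#'
#' @param wells Data frame with columns `cnr`, `cell_number`,
#'   `specific_activity` and optionally `qc_excluded`.
#' @param rule `"ci95_upper"` or `"rose"`.
#' @param cnr_threshold Threshold used by the `"rose"` rule (default 5).
#' @param lld_ci_at Specific activity at which the 95% CI is evaluated for
#'   the `"ci95_upper"` rule (default 0).
#'
#' @return An object of class `lld_result` with `cnr_threshold`,
#'   `lld_cells`, `lld_specific_activity`, `rule`, `n` and the two
#'   underlying [fit_line()] fits in `fits`.
#' @export
estimate_lld <- function(wells, rule = c("ci95_upper", "rose"),
                         cnr_threshold = 5, lld_ci_at = 0) {
  rule <- match.arg(rule)
  if ("qc_excluded" %in% names(wells)) {
    wells <- dplyr::filter(wells, !.data$qc_excluded)
  }
  if (nrow(wells) < 3L) {
    stop("need at least 3 unexcluded wells to estimate an LLD", call. = FALSE)
  }
  fit_sa <- fit_line(wells, .data$specific_activity, .data$cnr)
  fit_cells <- fit_line(wells, .data$cell_number, .data$cnr)
  thr <- if (rule == "ci95_upper") {
    ci_mean(fit_sa, lld_ci_at)$upr
  } else {
    cnr_threshold
  }
  if (fit_cells$slope <= 0 || fit_sa$slope <= 0) {
    stop("non-positive CNR regression slope: no finite LLD", call. = FALSE)
  }
  structure(
    list(
      cnr_threshold = thr,
      lld_cells = (thr - fit_cells$intercept) / fit_cells$slope,
      lld_specific_activity = (thr - fit_sa$intercept) / fit_sa$slope,
      rule = rule,
      n = nrow(wells),
      fits = list(cells = fit_cells, specific_activity = fit_sa)
    ),
    class = "lld_result"
  )
}

#' @export
print.lld_result <- function(x, ...) {
  cat(
    "<lld_result> rule = ", x$rule,
    ", CNR threshold = ", signif(x$cnr_threshold, 4),
    "\n  LLD: ", signif(x$lld_cells, 3), " cells; ",
    signif(x$lld_specific_activity, 3), " kBq/1e6 cells (n = ", x$n, ")\n",
    sep = ""
  )
  invisible(x)
}

#' Rose-criterion detectability classification
#'
#' A signal is classified as detected when its CNR reaches the Rose
#' threshold (inclusive; default 5).
#'
#' @param cnr_value Numeric CNR value(s); must be finite.
#' @param threshold Detection threshold (default 5).
#' @return Logical vector of detected flags.
#' @export
rose_classify <- function(cnr_value, threshold = 5) {
  if (any(!is.finite(cnr_value))) stop("CNR values must be finite", call. = FALSE)
  cnr_value >= threshold
}

#' Fit the logistic detection-probability model
#'
#' Maximum-likelihood binomial logistic regression of detection on cell
#' number: `P(detected) = 1 / (1 + exp(-(b0 + b1 * x)))`. On complete (or
#' quasi-complete) separation the unpenalized fit diverges; the function
#' then falls back to a ridge-penalized fit (penalty `1e-4` on the
#' standardized scale) and flags it via `separation = TRUE`.
#'
#' @param data A data frame.
#' @param x Unquoted cell-number column.
#' @param detected Unquoted logical (or 0/1) detection column.
#' @param ridge Ridge penalty used by the separation fallback.
#' @return An object of class `detection_curve` with `beta0`, `beta1`,
#'   `vcov`, `n`, `separation`.
#' @export
fit_logistic <- function(data, x, detected, ridge = 1e-4) {
  xv <- dplyr::pull(data, {{ x }})
  dv <- as.numeric(dplyr::pull(data, {{ detected }}))
  ok <- is.finite(xv) & is.finite(dv)
  xv <- xv[ok]; dv <- dv[ok]
  if (length(unique(dv)) < 2L) {
    stop("only one class present: detection curve inestimable", call. = FALSE)
  }
  sx <- stats::sd(xv)
  if (sx == 0) stop("degenerate predictor (singular fit)", call. = FALSE)
  xs <- xv / sx
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(dv ~ xs, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  # separation can also surface as huge finite coefficients without any
  # glm warning; |eta| beyond ~15 saturates the logistic
  if (!sep && fit$converged && max(abs(stats::coef(fit))) < 15) {
    b <- stats::coef(fit)
    V <- stats::vcov(fit)
  } else {
    rf <- ridge_logistic(cbind(1, xs), dv, ridge)
    b <- rf$beta
    V <- rf$vcov
    sep <- TRUE
  }
  scale_mat <- diag(c(1, 1 / sx))
  structure(
    list(
      beta0 = unname(b[1]),
      beta1 = unname(b[2]) / sx,
      vcov = scale_mat %*% V %*% scale_mat,
      n = length(xv),
      separation = sep,
      data = tibble::tibble(cell_number = xv, detected = as.logical(dv))
    ),
    class = "detection_curve"
  )
}

# Ridge-penalized logistic fit by iteratively reweighted least squares.
ridge_logistic <- function(X, y, lambda, max_iter = 200L, tol = 1e-10) {
  b <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% b)
    p <- stats::plogis(eta)
    W <- pmax(p * (1 - p), 1e-12)
    H <- crossprod(X, X * W) + diag(lambda, ncol(X))
    g <- crossprod(X, y - p) - lambda * b
    step <- solve(H, g)
    b <- b + drop(step)
    if (max(abs(step)) < tol) break
  }
  list(beta = b, vcov = solve(H))
}

#' @export
print.detection_curve <- function(x, ...) {
  cat(
    "<detection_curve> beta0 = ", signif(x$beta0, 4),
    ", beta1 = ", signif(x$beta1, 4), " per cell (n = ", x$n,
    if (x$separation) ", ridge fallback: separation" else "", ")\n",
    sep = ""
  )
  invisible(x)
}

#' Detection probability at a given cell number
#'
#' Evaluates the fitted logistic curve
#' `1 / (1 + exp(-(beta0 + beta1 * x)))`.
#'
#' @param curve A [fit_logistic()] result.
#' @param x Cell number(s); must be finite.
#' @return Probabilities in (0, 1).
#' @export
detection_probability <- function(curve, x) {
  stopifnot(inherits(curve, "detection_curve"))
  if (any(!is.finite(x))) stop("cell numbers must be finite", call. = FALSE)
  stats::plogis(curve$beta0 + curve$beta1 * x)
}

#' Cell number at a given detection probability
#'
#' Exact inverse of [detection_probability()]:
#' `x = (logit(p) - beta0) / beta1`.
#'
#' @param curve A [fit_logistic()] result.
#' @param p Probability in (0, 1).
#' @return Cell number.
#' @export
cells_at_probability <- function(curve, p) {
  stopifnot(inherits(curve, "detection_curve"))
  if (any(p <= 0 | p >= 1)) stop("p must be in (0, 1)", call. = FALSE)
  if (curve$beta1 == 0) stop("beta1 = 0: no solution", call. = FALSE)
  (stats::qlogis(p) - curve$beta0) / curve$beta1
}

#' Simulate non-specific background levels for each well
#'
#' For each included well and each background fraction `f`, sets the
#' background concentration to `f` times the well's signal concentration,
#' derives the background noise SD from a Poisson model
#' (`sigma_b = sqrt(k * mu_b)` with calibration constant `k`, the image-unit
#' variance per unit mean), recomputes the CNR and classifies detection by
#' the Rose criterion. The well signal concentration is `mu_w - mu_b` when a
#' measured background column `mu_b` is present, else `mu_w`.
#'
#' @param wells Data frame with columns `mu_w` (and optionally `mu_b`,
#'   `qc_excluded`, `well_id`, `cell_number`, `scanner`).
#' @param fractions Background fractions (default 0.10 to 0.80 by 0.10).
#' @param k Poisson calibration constant (> 0); see [estimate_poisson_k()].
#' @return A tibble of class `background_set` with one row per
#'   (well, fraction): `fraction`, `mu_well`, `mu_b_sim`, `sigma_b_sim`,
#'   `cnr`, `detected`, plus carried-through well columns.
#' @export
simulate_background_levels <- function(wells, fractions = seq(0.1, 0.8, by = 0.1),
                                       k = 1) {
  if (!(is.numeric(k) && length(k) == 1L && is.finite(k) && k > 0)) {
    stop("k must be a single positive number", call. = FALSE)
  }
  if (any(fractions <= 0 | fractions > 1)) {
    stop("fractions must lie in (0, 1]", call. = FALSE)
  }
  if (!("mu_w" %in% names(wells))) stop("`wells` needs a mu_w column", call. = FALSE)
  if ("qc_excluded" %in% names(wells)) {
    wells <- dplyr::filter(wells, !.data$qc_excluded)
  }
  mu_well <- if ("mu_b" %in% names(wells)) wells$mu_w - wells$mu_b else wells$mu_w
  keep <- is.finite(mu_well) & mu_well > 0
  if (!all(keep)) {
    stop("all included wells must have a positive signal concentration",
      call. = FALSE
    )
  }
  carry <- intersect(c("well_id", "plate_id", "scanner", "cell_number",
                       "specific_activity"), names(wells))
  base <- dplyr::mutate(wells[carry], mu_well = mu_well)
  out <- tidyr::crossing(base, fraction = fractions)
  out <- dplyr::mutate(
    out,
    mu_b_sim = .data$fraction * .data$mu_well,
    sigma_b_sim = sqrt(k * .data$mu_b_sim),
    cnr = (.data$mu_well - .data$mu_b_sim) / .data$sigma_b_sim,
    detected = rose_classify(.data$cnr)
  )
  class(out) <- c("background_set", class(out))
  attr(out, "k") <- k
  out
}

#' Estimate the Poisson calibration constant from measured background
#'
#' Under a variance-proportional-to-mean noise model, `k = sigma^2 / mu` of
#' the background voxel values. Given a quantified well table this returns
#' the median of `sigma_b^2 / mu_b` over its plate backgrounds.
#'
#' @param wells Data frame with `mu_b` and `sigma_b` columns (one estimate
#'   per plate, repeated across its wells), or a `background_estimate`.
#' @return The calibration constant `k` (kBq/mL of variance per kBq/mL of
#'   mean).
#' @export
estimate_poisson_k <- function(wells) {
  if (inherits(wells, "background_estimate")) {
    return(wells$sigma_b^2 / wells$mu_b)
  }
  stopifnot(all(c("mu_b", "sigma_b") %in% names(wells)))
  stats::median(wells$sigma_b^2 / wells$mu_b, na.rm = TRUE)
}

#' Detection probability as a function of background level
#'
#' Fits one logistic detection curve per background fraction of a
#' [simulate_background_levels()] result and evaluates the cell number
#' needed for 90% detection probability at each fraction. Fractions whose
#' detection flags are single-class are flagged `inestimable` rather than
#' failing.
#'
#' @param background_set A [simulate_background_levels()] result.
#' @param p Probability at which the required cell number is evaluated
#'   (default 0.9).
#' @return A tibble of class `background_detection`: `fraction`, `beta0`,
#'   `beta1`, `separation`, `inestimable`, `cells_at_p`, with the fitted
#'   curves in attribute `"curves"`.
#' @export
detection_vs_background <- function(background_set, p = 0.9) {
  stopifnot(inherits(background_set, "background_set"))
  if (!("cell_number" %in% names(background_set))) {
    stop("`background_set` needs a cell_number column", call. = FALSE)
  }
  fracs <- sort(unique(background_set$fraction))
  curves <- list()
  rows <- lapply(fracs, function(f) {
    d <- dplyr::filter(background_set, .data$fraction == f)
    if (length(unique(d$detected)) < 2L) {
      return(tibble::tibble(
        fraction = f, beta0 = NA_real_, beta1 = NA_real_,
        separation = NA, inestimable = TRUE, cells_at_p = NA_real_
      ))
    }
    cv <- fit_logistic(d, .data$cell_number, .data$detected)
    curves[[as.character(f)]] <<- cv
    tibble::tibble(
      fraction = f, beta0 = cv$beta0, beta1 = cv$beta1,
      separation = cv$separation, inestimable = FALSE,
      cells_at_p = cells_at_probability(cv, p)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("background_detection", class(out))
  attr(out, "curves") <- curves
  attr(out, "p") <- p
  out
}
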