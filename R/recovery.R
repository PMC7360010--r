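#' Recovery coefficient of a well
#'
#' Background-corrected image activity divided by the true (well-counter)
#' activity: `rc = (measured_well - measured_background) / known_well`, with
#' the known background activity fixed at 0 kBq. Values below 0 or above 1
#' are legitimate under noise and are not clipped.
#'
#' @param measured_well Total image activity in the well VOI, kBq.
#' @param measured_background Total image activity in a same-size background
#'   VOI, kBq.
#' @param known_well Well-counter activity, kBq; must be positive.
#' @return Dimensionless recovery coefficient (vectorized).
#' @export
#' @examples
#' recovery_coefficient(8, 0.4, 9.5) # 0.8
recovery_coefficient <- function(measured_well, measured_background, known_well) {
  if (any(!is.finite(known_well)) || any(known_well <= 0)) {
    stop("known_well must be positive (undefined RC)", call. = FALSE)
  }
  (measured_well - measured_background) / known_well
}

#' Construct a recovery-coefficient model from known coefficients
#'
#' Builds an `rc_fit` object directly from a slope and intercept (natural
#' log), e.g. coefficients read off a published fit, so that
#' [predict_rc()] and [density_for_rc()] can be applied without refitting.
#'
#' @param slope Slope of RC on `log(CD * SA)` (natural log).
#' @param intercept Population intercept.
#' @param ranef Named per-scanner intercept offsets (default all zero).
#' @param sigma Residual SD, if known.
#' @return An object of class `rc_fit`.
#' @export
rc_fit <- function(slope, intercept, ranef = c(petct = 0, petmri = 0),
                   sigma = NA_real_) {
  structure(
    list(
      slope = slope, intercept = intercept, ranef = ranef,
      sigma = sigma, n = NA_integer_, method = "fixed", data = NULL
    ),
    class = "rc_fit"
  )
}

#' Fit the log-linear recovery-coefficient model
#'
#' Fits `RC = a * ln(CD * SA) + g0 + u_i + e` with a shared fixed slope `a`,
#' population intercept `g0`, per-scanner random intercepts `u_i` and
#' residual error `e`, where CD is cell density (10^6 cells/mL) and SA is
#' specific activity (kBq per 10^6 cells), so `CD * SA` is the activity
#' concentration of the suspension in kBq/mL. The natural log is used
#' throughout.
#'
#' Estimation is maximum likelihood via [lme4::lmer()]. With only two
#' scanner groups the random-intercept variance can collapse to zero
#' (singular fit); in that case a documented fallback estimates `u_i` as
#' shrunk per-scanner intercept deviations from a fixed-effects fit
#' (shrinkage factor `max(0, 1 - within-variance / between-variance)`) and
#' flags the method as `"shrunk"`. With a single scanner the model
#' degenerates to ordinary regression with a warning.
#'
#' @param data Data frame with columns `rc`, `cell_density`,
#'   `specific_activity`, `scanner`.
#' @return An object of class `rc_fit`: `slope`, `intercept`, `ranef`
#'   (named per-scanner offsets, centered), `sigma`, `n`, `method`
#'   (`"lmer"`, `"shrunk"` or `"ols"`), and the model frame in `data`.
#' @export
fit_rc_model <- function(data) {
  need <- c("rc", "cell_density", "specific_activity", "scanner")
  if (!all(need %in% names(data))) {
    stop("`data` needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  prod_csa <- data$cell_density * data$specific_activity
  if (any(!is.finite(prod_csa)) || any(prod_csa <= 0)) {
    stop("CD * SA must be positive for every observation (domain error)",
      call. = FALSE
    )
  }
  df <- data.frame(
    rc = data$rc, x = log(prod_csa),
    scanner = factor(data$scanner)
  )
  groups <- levels(df$scanner)
  tab <- table(df$scanner)
  if (any(tab < 3L)) {
    stop("need at least 3 observations per scanner", call. = FALSE)
  }
  if (length(groups) < 2L) {
    warning("single scanner: degenerating to ordinary regression")
    fit <- stats::lm(rc ~ x, data = df)
    u <- stats::setNames(0, groups)
    res <- list(
      slope = unname(stats::coef(fit)["x"]),
      intercept = unname(stats::coef(fit)["(Intercept)"]),
      ranef = u, sigma = quiet_lm_sigma(fit), method = "ols"
    )
  } else {
    lfit <- suppressMessages(lme4::lmer(
      rc ~ x + (1 | scanner), data = df, REML = FALSE,
      control = lme4::lmerControl(check.conv.singular = "ignore", calc.derivs = FALSE)
    ))
    if (lme4::isSingular(lfit, tol = 1e-5)) {
      res <- rc_shrunk_fallback(df)
    } else {
      re <- lme4::ranef(lfit)$scanner
      u <- stats::setNames(re[, "(Intercept)"], rownames(re))
      fe <- lme4::fixef(lfit)
      res <- list(
        slope = unname(fe["x"]), intercept = unname(fe["(Intercept)"]),
        ranef = u[groups], sigma = stats::sigma(lfit), method = "lmer"
      )
    }
  }
  structure(
    c(res, list(n = nrow(df), data = tibble::as_tibble(df))),
    class = "rc_fit"
  )
}

# Fallback when the two-group random-intercept variance is estimated as
# zero: per-scanner intercept deviations from a sum-contrast fixed-effects
# fit, shrunk toward zero by an empirical-Bayes factor.
rc_shrunk_fallback <- function(df) {
  fit0 <- stats::lm(rc ~ x, data = df)
  resid_g <- tapply(stats::resid(fit0), df$scanner, mean)
  d <- resid_g - mean(resid_g)
  n_g <- as.numeric(table(df$scanner))
  s2 <- quiet_lm_sigma(fit0)^2
  var_d <- mean(d^2)
  lam <- if (var_d > 0) max(0, 1 - s2 * mean(1 / n_g) / var_d) else 0
  u <- lam * d
  list(
    slope = unname(stats::coef(fit0)["x"]),
    intercept = unname(stats::coef(fit0)["(Intercept)"]),
    ranef = stats::setNames(as.numeric(u), names(d)),
    sigma = quiet_lm_sigma(fit0), method = "shrunk"
  )
}

#' @export
print.rc_fit <- function(x, ...) {
  cat(
    "<rc_fit> RC = ", signif(x$slope, 4), " * ln(CD*SA) + ",
    signif(x$intercept, 4), "  [", x$method, "]\n", sep = ""
  )
  if (length(x$ranef)) {
    cat("  scanner offsets:",
        paste(names(x$ranef), signif(x$ranef, 3), sep = " = ", collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Predict a recovery coefficient from the fitted model
#'
#' `rc = a * ln(CD * SA) + g0 (+ u_i)`. Predictions are not clipped;
#' values outside \[0, 1\] are returned as-is with attribute
#' `"out_of_range"` flagging them.
#'
#' @param fit An [rc_fit] object.
#' @param cell_density CD in 10^6 cells/mL (vectorized).
#' @param specific_activity SA in kBq per 10^6 cells (vectorized).
#' @param scanner Optional scanner id whose intercept offset to include;
#'   `NULL` gives the population prediction.
#' @return Predicted recovery coefficient(s).
#' @export
#' @examples
#' predict_rc(rc_fit(0.11, 0.57), 1, 1) # 0.57
predict_rc <- function(fit, cell_density, specific_activity, scanner = NULL) {
  stopifnot(inherits(fit, "rc_fit"))
  prod_csa <- cell_density * specific_activity
  if (any(!is.finite(prod_csa)) || any(prod_csa <= 0)) {
    stop("CD * SA must be positive (domain error)", call. = FALSE)
  }
  u <- 0
  if (!is.null(scanner)) {
    if (!(scanner %in% names(fit$ranef))) {
      stop("unknown scanner: ", scanner, call. = FALSE)
    }
    u <- fit$ranef[[scanner]]
  }
  out <- fit$slope * log(prod_csa) + fit$intercept + u
  attr(out, "out_of_range") <- out < 0 | out > 1
  out
}

#' Cell density required to reach a target recovery coefficient
#'
#' Exact inverse of [predict_rc()] in cell density:
#' `CD = exp((target_rc - intercept) / slope) / SA`.
#'
#' @param fit An [rc_fit] object with positive slope.
#' @param target_rc Target recovery coefficient.
#' @param specific_activity SA in kBq per 10^6 cells; must be positive.
#' @param scanner Optional scanner id whose intercept offset to include.
#' @return Required cell density in 10^6 cells/mL.
#' @export
#' @examples
#' density_for_rc(rc_fit(0.11, 0.57), 1, 5.3) # ~9.4 (x 10^6 cells/mL)
density_for_rc <- function(fit, target_rc, specific_activity, scanner = NULL) {
  stopifnot(inherits(fit, "rc_fit"))
  if (fit$slope <= 0) stop("non-positive slope: no solution", call. = FALSE)
  if (any(specific_activity <= 0)) {
    stop("specific_activity must be positive", call. = FALSE)
  }
  u <- 0
  if (!is.null(scanner)) {
    if (!(scanner %in% names(fit$ranef))) {
      stop("unknown scanner: ", scanner, call. = FALSE)
    }
    u <- fit$ranef[[scanner]]
  }
  exp((target_rc - (fit$intercept + u)) / fit$slope) / specific_activity
}


# residual SD of an lm fit without the perfect-fit warning (exact data is a
# valid input for these models)
quiet_lm_sigma <- function(fit) {
  withCallingHandlers(
    summary(fit)$sigma,
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
}
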