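test_that("line fit recovers exact and noisy linear relationships", {
  d <- tibble::tibble(x = c(0, 1, 2, 5, 9), y = 2 * c(0, 1, 2, 5, 9) + 1)
  f <- fit_line(d, x, y)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$sigma, 0, tolerance = 1e-12)
  ci <- ci_mean(f, 4)
  expect_equal(ci$upr - ci$lwr, 0, tolerance = 1e-10)

  expect_error(fit_line(tibble::tibble(x = 1:2, y = 1:2), x, y), "at least 3")
  expect_error(fit_line(tibble::tibble(x = c(1, 1, 1), y = 1:3), x, y),
               "singular")

  noisy <- withr::with_seed(5, {
    x <- stats::runif(1000, 0, 10)
    tibble::tibble(x = x, y = 3 * x + stats::rnorm(1000))
  })
  fn <- fit_line(noisy, x, y)
  expect_gt(fn$slope, 2.9)
  expect_lt(fn$slope, 3.1)
})

test_that("LLD inverts the CNR regressions at the detection threshold", {
  # exact line CNR = 0.01 * cells with zero residuals; Rose threshold 5
  wells <- tibble::tibble(
    cell_number = c(100, 200, 400, 800),
    specific_activity = c(1, 2, 4, 8),
    cnr = 0.01 * c(100, 200, 400, 800)
  )
  res <- estimate_lld(wells, rule = "rose")
  expect_equal(res$cnr_threshold, 5)
  expect_equal(res$lld_cells, 500)

  excl <- dplyr::mutate(wells, qc_excluded = TRUE)
  expect_error(estimate_lld(excl), "at least 3")

  flat <- dplyr::mutate(wells, cnr = 1)
  expect_error(estimate_lld(flat, rule = "rose"), "singular|slope")
})

test_that("estimate_lld matches an independently coded four-step oracle", {
  # closed-form OLS + t-quantile oracle, no lm/predict
  lld_oracle <- function(wells, ci_at = 0) {
    ols <- function(x, y) {
      n <- length(x)
      sxx <- sum((x - mean(x))^2)
      b <- sum((x - mean(x)) * (y - mean(y))) / sxx
      a <- mean(y) - b * mean(x)
      res <- y - (a + b * x)
      s2 <- sum(res^2) / (n - 2)
      list(a = a, b = b, s2 = s2, n = n, sxx = sxx, xbar = mean(x))
    }
    f_sa <- ols(wells$specific_activity, wells$cnr)
    f_ce <- ols(wells$cell_number, wells$cnr)
    se_mean <- sqrt(f_sa$s2 * (1 / f_sa$n + (ci_at - f_sa$xbar)^2 / f_sa$sxx))
    thr <- f_sa$a + f_sa$b * ci_at +
      stats::qt(0.975, f_sa$n - 2) * se_mean
    list(
      thr = thr,
      cells = (thr - f_ce$a) / f_ce$b,
      sa = (thr - f_sa$a) / f_sa$b,
      slope_sa = f_sa$b, slope_cells = f_ce$b
    )
  }
  for (i in 1:50) {
    wells <- withr::with_seed(1000 + i, {
      n <- sample(5:40, 1)
      cells <- stats::rlnorm(n, log(2e5), 1)
      sa <- stats::rlnorm(n, log(5), 0.8)
      tibble::tibble(
        cell_number = cells,
        specific_activity = sa,
        cnr = 1e-4 * cells + 3 * sa + stats::rnorm(n, 0, 5)
      )
    })
    want <- lld_oracle(wells)
    slopes_ok <- want$slope_sa > 0 && want$slope_cells > 0
    if (!slopes_ok) {
      # a non-positive sample slope admits no finite LLD
      expect_error(estimate_lld(wells), "no finite LLD")
      next
    }
    got <- estimate_lld(wells)
    expect_equal(got$cnr_threshold, want$thr, tolerance = 1e-9)
    expect_equal(got$lld_cells, want$cells, tolerance = 1e-9)
    expect_equal(got$lld_specific_activity, want$sa, tolerance = 1e-9)
  }
})

test_that("Rose classification uses an inclusive threshold of 5", {
  expect_true(rose_classify(5))
  expect_false(rose_classify(4.999))
  expect_true(rose_classify(2106))
  expect_error(rose_classify(NaN), "finite")
})

test_that("logistic fit recovers known coefficients and flags degenerate input", {
  b0 <- -4; b1 <- 1e-5
  d <- withr::with_seed(17, {
    x <- stats::runif(5000, 0, 1.5e6)
    p <- stats::plogis(b0 + b1 * x)
    tibble::tibble(cell_number = x, detected = stats::rbinom(5000, 1, p) == 1)
  })
  cv <- fit_logistic(d, cell_number, detected)
  expect_equal(cv$beta0, b0, tolerance = 0.1)
  expect_equal(cv$beta1, b1, tolerance = 0.1)
  expect_false(cv$separation)

  all_on <- tibble::tibble(cell_number = 1:10, detected = TRUE)
  expect_error(fit_logistic(all_on, cell_number, detected), "one class")

  # permutation invariance
  perm <- withr::with_seed(3, sample.int(nrow(d)))
  cv2 <- fit_logistic(d[perm, ], cell_number, detected)
  expect_equal(cv2$beta0, cv$beta0, tolerance = 1e-8)
  expect_equal(cv2$beta1, cv$beta1, tolerance = 1e-8)

  # complete separation falls back to a flagged ridge fit
  sep <- tibble::tibble(cell_number = c(1:10, 101:110),
                        detected = rep(c(FALSE, TRUE), each = 10))
  cvs <- fit_logistic(sep, cell_number, detected)
  expect_true(cvs$separation)
  expect_true(is.finite(cvs$beta1) && cvs$beta1 > 0)
})

test_that("detection probability and its inverse are consistent", {
  cv <- structure(
    list(beta0 = log(9), beta1 = 0, vcov = diag(2), n = 10,
         separation = FALSE, data = NULL),
    class = "detection_curve"
  )
  expect_equal(detection_probability(cv, 123), 0.9)

  cv2 <- structure(
    list(beta0 = -4.59512, beta1 = 1e-5, vcov = diag(2), n = 10,
         separation = FALSE, data = NULL),
    class = "detection_curve"
  )
  expect_equal(detection_probability(cv2, -cv2$beta0 / cv2$beta1), 0.5)
  # x at 90% = (ln 9 + 4.59512) / 1e-5
  expect_equal(cells_at_probability(cv2, 0.9), (log(9) + 4.59512) / 1e-5)
  expect_equal(cells_at_probability(cv2, 0.9), 679234.5, tolerance = 1e-6)

  for (p in c(0.1, 0.5, 0.9, 0.99)) {
    expect_equal(detection_probability(cv2, cells_at_probability(cv2, p)), p,
                 tolerance = 1e-12)
  }
  # strictly increasing when beta1 > 0
  xs <- seq(0, 2e6, length.out = 50)
  expect_true(all(diff(detection_probability(cv2, xs)) > 0))

  expect_error(cells_at_probability(cv, 0.9), "no solution")
  expect_error(cells_at_probability(cv2, 1), "in \\(0, 1\\)")
})

test_that("background simulation follows the Poisson CNR formula exactly", {
  wells <- withr::with_seed(9, tibble::tibble(
    well_id = sprintf("W%02d", 1:31),
    cell_number = round(stats::rlnorm(31, log(2e5), 1)),
    mu_w = stats::rlnorm(31, log(0.05), 1.2)
  ))
  k <- 0.001
  bg <- simulate_background_levels(wells, k = k)
  expect_equal(nrow(bg), 31 * 8)
  expect_equal(bg$cnr,
               bg$mu_well * (1 - bg$fraction) / sqrt(k * bg$fraction * bg$mu_well))

  # CNR strictly decreasing in f for every well
  dec <- dplyr::summarise(dplyr::group_by(bg, well_id),
                          mono = all(diff(cnr[order(fraction)]) < 0))
  expect_true(all(dec$mono))

  # f = 1 edge: CNR = 0
  edge <- simulate_background_levels(wells, fractions = 1, k = k)
  expect_equal(edge$cnr, rep(0, 31))

  expect_error(simulate_background_levels(wells, k = 0), "positive")

  # measured background is removed from the well concentration when present
  wells2 <- dplyr::mutate(wells, mu_b = 0.2 * mu_w)
  bg2 <- simulate_background_levels(wells2, k = k)
  expect_equal(sort(unique(bg2$mu_well)), sort(0.8 * wells$mu_w))
})

test_that("doubling well concentrations rescales CNR by sqrt(2)", {
  wells <- tibble::tibble(
    well_id = sprintf("W%02d", 1:20),
    cell_number = seq(1e4, 1e6, length.out = 20),
    mu_w = seq(0.005, 0.5, length.out = 20)
  )
  b1 <- simulate_background_levels(wells, k = 0.001)
  b2 <- simulate_background_levels(dplyr::mutate(wells, mu_w = 2 * mu_w),
                                   k = 0.001)
  expect_equal(b2$cnr, sqrt(2) * b1$cnr, tolerance = 1e-12)
  expect_gte(sum(b2$detected), sum(b1$detected))
})

test_that("per-fraction detection fits flag inestimable fractions without failing", {
  wells <- tibble::tibble(
    well_id = sprintf("W%02d", 1:10),
    cell_number = seq(1e4, 1e6, length.out = 10),
    mu_w = rep(1e6, 10) # so large that everything is detected at every f
  )
  bg <- simulate_background_levels(wells, k = 1e-3)
  dv <- detection_vs_background(bg)
  expect_true(all(dv$inestimable))
  expect_true(all(is.na(dv$cells_at_p)))
})
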