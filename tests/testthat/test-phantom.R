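test_that("plate_spec records derived truth activity and validates input", {
  p <- one_well_plate(1e6, 10)
  expect_equal(p$truth_kBq, 10)

  cu <- plate_spec("cubic_3x3", cubic_plate_default_wells())
  # 3.25e4 cells at 15.41 kBq/1e6 cells
  expect_equal(cu$truth_kBq[cu$well_id == "M2"], 3.25e4 * 15.41 / 1e6)
  expect_equal(cu$truth_kBq[cu$well_id == "M2"], 0.501, tolerance = 2e-3)
  # cubic wells are 1 mL, so density (1e6 cells/mL) = cells / 1e6
  expect_equal(cu$cell_density, cu$cell_number / 1e6)

  expect_error(
    plate_spec("six_well", tibble::tibble(
      cell_number = rep(1e5, 7), specific_activity = 1
    )),
    "capacity"
  )
  expect_error(
    plate_spec("six_well", tibble::tibble(
      cell_number = -1, specific_activity = 1
    )),
    "non-negative"
  )
})

test_that("rasterization fills shapes uniformly and conserves activity exactly", {
  # 1 kBq in a 1 cm^3 cube on a 1 mm grid: 1000 voxels at 1.0 kBq/mL
  cu <- plate_spec("cubic_3x3", tibble::tibble(
    cell_number = 1e6, specific_activity = 1
  ))
  img <- rasterize_truth(cu)
  vals <- img$voxels[img$voxels > 0]
  expect_length(vals, 1000)
  expect_true(all(vals == vals[1]))
  expect_equal(vals[1], 1.0)
  expect_equal(total_activity(img), 1.0)

  # empty plate -> all-zero image
  empty <- plate_spec("six_well",
    tibble::tibble(cell_number = numeric(), specific_activity = numeric())
  )
  expect_true(all(rasterize_truth(empty)$voxels == 0))

  # conservation with several wells
  p <- plate_spec("six_well", tibble::tibble(
    cell_number = c(7e5, 3e5), specific_activity = c(10, 10)
  ))
  expect_equal(total_activity(rasterize_truth(p)), 10)
})

test_that("Gaussian blur matches a brute-force convolution oracle", {
  # independent direct-sum separable convolution on a small array
  brute_blur <- function(v, sig) {
    for (ax in 1:3) {
      n <- dim(v)[ax]
      r <- as.integer(ceiling(3.5 * sig))
      off <- -r:r
      w <- exp(-off^2 / (2 * sig^2))
      w <- w / sum(w)
      out <- array(0, dim(v))
      for (m in seq_along(off)) {
        src <- seq_len(n) - off[m]
        ok <- src >= 1 & src <= n
        idx_to <- which(ok)
        idx_from <- src[ok]
        if (ax == 1) out[idx_to, , ] <- out[idx_to, , ] + w[m] * v[idx_from, , ]
        if (ax == 2) out[, idx_to, ] <- out[, idx_to, ] + w[m] * v[, idx_from, ]
        if (ax == 3) out[, , idx_to] <- out[, , idx_to] + w[m] * v[, , idx_from]
      }
      v <- out
    }
    v
  }
  set.seed(11)
  v <- array(stats::runif(20 * 18 * 16), c(20, 18, 16))
  fwhm <- 4
  sig <- fwhm / (2 * sqrt(2 * log(2)))
  got <- petlimit:::blur_gaussian(v, fwhm, c(1, 1, 1))
  expect_equal(got, brute_blur(v, sig), tolerance = 1e-12)
})

test_that("blur conserves total activity and spills activity out of the well VOI", {
  cu <- plate_spec("cubic_3x3", tibble::tibble(
    cell_number = 1e6, specific_activity = 1
  ))
  truth <- rasterize_truth(cu, padding = 18)
  scan <- simulate_scan(truth, noiseless_scanner(fwhm = 6))
  expect_equal(total_activity(scan), 1.0, tolerance = 1e-3)
  voi <- make_voi(scan, "cube", center = c(cu$x[1], cu$y[1], cu$z[1]), edge = 10)
  expect_lt(voi_total_activity(scan, voi), 1.0)

  # recovered fraction is non-increasing in PSF FWHM (noiseless)
  rec <- vapply(c(0, 2, 4, 6, 8), function(fw) {
    s <- simulate_scan(truth, noiseless_scanner(fwhm = fw))
    voi_total_activity(s, voi)
  }, 0)
  expect_true(all(diff(rec) <= 1e-12))
})

test_that("simulate_scan limiting cases and reproducibility behave as specified", {
  p <- one_well_plate(1e6, 1)
  truth <- rasterize_truth(p)

  # zero truth, zero background -> zero image
  z <- rasterize_truth(one_well_plate(0, 0))
  expect_true(all(simulate_scan(z, noiseless_scanner())$voxels == 0))

  # identity limit: no blur, no noise -> truth plus background inside support
  sc <- noiseless_scanner(fwhm = 0, bg = 0.5)
  out <- simulate_scan(truth, sc)
  mask <- petlimit:::support_mask(truth)
  expect_equal(out$voxels[mask], truth$voxels[mask] + 0.5)
  expect_equal(out$voxels[!mask], truth$voxels[!mask])

  # same seed -> identical image; different seed -> different
  noisy <- scanner_model("petct", psf_fwhm = 0,
                         background_concentration = 0.01, noise_scale = 500)
  s1 <- simulate_scan(truth, noisy, seed = 5)
  s2 <- simulate_scan(truth, noisy, seed = 5)
  s3 <- simulate_scan(truth, noisy, seed = 6)
  expect_identical(s1$voxels, s2$voxels)
  expect_false(identical(s1$voxels, s3$voxels))

  expect_error(simulate_scan(truth, noisy), "seed")
})

test_that("well counter error model has the stated mean and spread", {
  p <- one_well_plate(1e6, 10) # truth 10 kBq
  expect_equal(simulate_well_counter(p, counter_cv = 0)$counter_kBq, 10)

  p0 <- one_well_plate(0, 0)
  expect_equal(simulate_well_counter(p0, counter_cv = 0.5, seed = 1)$counter_kBq, 0)

  meas <- vapply(seq_len(1e4), function(s) {
    simulate_well_counter(p, counter_cv = 0.05, seed = s)$counter_kBq
  }, 0)
  expect_equal(mean(meas), 10, tolerance = 0.002)
  expect_equal(stats::sd(meas), 0.5, tolerance = 0.05)
})

test_that("generated study reproduces the design counts and is deterministic", {
  wells <- default_study_wells()
  six <- dplyr::filter(wells, layout == "six_well")
  for (a in unique(six$scanner)) {
    arm <- dplyr::filter(six, scanner == a)
    expect_equal(nrow(arm), 36L)
    expect_equal(sum(!arm$qc_excluded), 31L)
  }

  s1 <- generate_study(small_config(seed = 99))
  s2 <- generate_study(small_config(seed = 99))
  expect_identical(s1$counter, s2$counter)
  expect_identical(
    s1$scans[[1]][["petct"]]$voxels,
    s2$scans[[1]][["petct"]]$voxels
  )

  # collapsed specific-activity range
  cfg <- study_config(plates_per_arm = 2L, n_excluded = 1L,
                      sa_range = c(3, 3), include_cubic = FALSE, seed = 3)
  st <- generate_study(cfg)
  expect_true(all(st$counter$specific_activity == 3))
})

test_that("generated CNR correlates strongly with well activity", {
  six <- dplyr::filter(default_study_wells(), layout == "six_well",
                       !qc_excluded)
  for (a in unique(six$scanner)) {
    arm <- dplyr::filter(six, scanner == a)
    expect_gt(pearson(arm, truth_kBq, cnr)$r, 0.7)
  }
})
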