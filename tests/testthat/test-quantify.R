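test_that("VOI membership counts match brute-force voxel-center counting", {
  img <- activity_image(array(0, c(60, 60, 40)))

  v <- make_voi(img, "cube", center = c(30, 30, 20), edge = 10)
  expect_equal(v$n_voxels, 1000L)
  expect_equal(v$volume_ml, 1.0)

  # brute-force oracle: integer voxel centers strictly inside radius 17
  disc_count <- sum(outer((-25:25)^2, (-25:25)^2, `+`) < 17^2)
  v2 <- make_voi(img, "cylinder", center = c(30, 30, 20),
                 diameter = 34, height = 1)
  expect_equal(v2$n_voxels, disc_count)
  expect_equal(disc_count, 889L)

  expect_error(
    make_voi(img, "cube", center = c(200, 30, 20), edge = 10),
    "geometry"
  )
})

test_that("VOI total activity is mean concentration times volume and is linear", {
  img <- activity_image(array(0.5, c(30, 30, 30)))
  v <- make_voi(img, "cube", center = c(15, 15, 15), edge = 10)
  expect_equal(voi_total_activity(img, v), 0.5)

  zero <- activity_image(array(0, c(30, 30, 30)))
  expect_equal(voi_total_activity(zero, v), 0)

  # noiseless rasterized 1 kBq well fully inside its VOI, no blur
  cu <- plate_spec("cubic_3x3", tibble::tibble(
    cell_number = 1e6, specific_activity = 1
  ))
  truth <- rasterize_truth(cu)
  voi <- make_voi(truth, "cube", center = c(cu$x[1], cu$y[1], cu$z[1]), edge = 10)
  expect_equal(voi_total_activity(truth, voi), 1.0)

  # linearity in the image
  set.seed(2)
  i1 <- activity_image(array(stats::runif(27e3), c(30, 30, 30)))
  i2 <- activity_image(array(stats::runif(27e3), c(30, 30, 30)))
  comb <- activity_image(2 * i1$voxels + 3 * i2$voxels)
  expect_equal(
    voi_total_activity(comb, v),
    2 * voi_total_activity(i1, v) + 3 * voi_total_activity(i2, v)
  )
})

test_that("background statistics pool voxels with sample SD", {
  img <- activity_image(array(0.7, c(20, 20, 20)))
  v <- make_voi(img, "cube", center = c(10, 10, 10), edge = 6)
  bg <- background_stats(img, v)
  expect_equal(bg$mu_b, 0.7)
  expect_equal(bg$sigma_b, 0)

  # two-point SD with denominator n - 1
  img2 <- activity_image(array(c(1, 3), c(2, 1, 1)))
  v2 <- make_voi(img2, "cube", center = c(0.5, 0, 0), edge = 2)
  bg2 <- background_stats(img2, v2)
  expect_equal(bg2$mu_b, 2)
  expect_equal(bg2$sigma_b, sqrt(2))

  img3 <- activity_image(array(1, c(1, 1, 1)))
  v3 <- make_voi(img3, "cube", center = c(0, 0, 0), edge = 1)
  expect_error(background_stats(img3, v3), "degenerate")
})

test_that("Poisson-noised background variance matches the noise model", {
  # sigma^2 of voxel values should be ~ mu / noise_scale
  p <- one_well_plate(0, 0)
  truth <- rasterize_truth(p)
  sc <- scanner_model("petct", psf_fwhm = 0, background_concentration = 0.5,
                      noise_scale = 200)
  scan <- simulate_scan(truth, sc, seed = 31)
  vals <- scan$voxels[petlimit:::support_mask(truth)]
  expect_equal(mean(vals), 0.5, tolerance = 0.01)
  expect_equal(stats::var(vals), 0.5 / 200, tolerance = 0.05)
  expect_equal(estimate_poisson_k(
    tibble::tibble(mu_b = mean(vals), sigma_b = stats::sd(vals))
  ), 1 / 200, tolerance = 0.05)
})

test_that("CNR definition, degenerate cases and gain invariance hold", {
  expect_equal(cnr(2, 2, 1), 0)
  expect_equal(cnr(12, 2, 5), 2)
  expect_error(cnr(1, 0, 0), "undefined")
  expect_equal(cnr(-1, 2, 5, clip_at_zero = TRUE), 0)

  # affine gain applied jointly leaves CNR unchanged
  g <- 3.7
  expect_equal(cnr(g * 12, g * 2, g * 5), cnr(12, 2, 5))
})

test_that("quantify_plate reproduces truth exactly on noiseless unblurred scans", {
  for (layout in c("six_well", "cubic_3x3")) {
    wells_in <- if (layout == "six_well") {
      tibble::tibble(cell_number = c(1e6, 2e5), specific_activity = c(5, 8))
    } else {
      cubic_plate_default_wells()
    }
    p <- plate_spec(layout, wells_in)
    truth <- rasterize_truth(p)
    scan <- simulate_scan(truth, noiseless_scanner(fwhm = 0, bg = 0.01))
    q <- quantify_plate(scan, p)
    # background-corrected activity equals truth to machine precision
    rc <- recovery_coefficient(q$image_kBq, q$background_kBq, p$truth_kBq)
    expect_equal(rc, rep(1, nrow(p)), tolerance = 1e-12)
  }

  empty <- plate_spec("six_well",
    tibble::tibble(cell_number = numeric(), specific_activity = numeric())
  )
  img <- activity_image(array(0, c(10, 10, 10)))
  expect_equal(nrow(quantify_plate(img, empty)), 0L)
})

test_that("image activity tracks counter activity across the default study", {
  six <- dplyr::filter(default_study_wells(), layout == "six_well",
                       !qc_excluded)
  for (a in unique(six$scanner)) {
    arm <- dplyr::filter(six, scanner == a)
    expect_gt(pearson(arm, counter_kBq, image_kBq)$r, 0.8)
  }
})
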