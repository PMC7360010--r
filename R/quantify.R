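#' Define a volume of interest on an image grid
#'
#' A VOI is the set of voxels whose centers fall inside a cylinder (stacked
#' circular discs along the plate-normal axis) or an axis-aligned cube. Its
#' volume is the member-voxel count times the voxel volume.
#'
#' @param image An [activity_image()] providing the grid.
#' @param shape `"cylinder"` or `"cube"`.
#' @param center World coordinates of the VOI center, mm.
#' @param diameter,height Cylinder dimensions, mm.
#' @param edge Cube edge, mm.
#'
#' @return An object of class `voi` with fields `indices`, `n_voxels`,
#'   `volume_ml` and the defining shape.
#' @export
#' @examples
#' img <- activity_image(array(0.5, c(30, 30, 30)))
#' v <- make_voi(img, "cube", center = c(14.5, 14.5, 14.5), edge = 10)
#' v$n_voxels # 1000
make_voi <- function(image, shape = c("cylinder", "cube"), center,
                     diameter = NULL, height = NULL, edge = NULL) {
  stopifnot(inherits(image, "activity_image"))
  shape <- match.arg(shape)
  lo <- image$origin
  hi <- image$origin + (dim(image$voxels) - 1) * image$voxel_size
  if (any(center < lo) || any(center > hi)) {
    stop("VOI center lies outside the image (geometry error)", call. = FALSE)
  }
  sh <- if (shape == "cube") {
    list(type = "cube", center = center, edge = edge)
  } else {
    list(type = "cylinder", center = center, diameter = diameter, height = height)
  }
  idx <- shape_voxel_indices(image, sh)
  if (length(idx) == 0L) {
    stop("VOI contains no voxels on this grid (geometry error)", call. = FALSE)
  }
  structure(
    list(
      indices = idx, n_voxels = length(idx),
      volume_ml = length(idx) * voxel_volume_ml(image), shape = sh
    ),
    class = "voi"
  )
}

#' Total activity inside a VOI
#'
#' Mean concentration over the member voxels times the VOI volume
#' (equivalently, the sum of concentrations times the voxel volume).
#'
#' @param image An [activity_image()].
#' @param voi A [make_voi()] object defined on the same grid.
#' @return Activity in kBq.
#' @export
voi_total_activity <- function(image, voi) {
  stopifnot(inherits(voi, "voi"))
  if (max(voi$indices) > length(image$voxels)) {
    stop("VOI indices exceed the image (grid mismatch)", call. = FALSE)
  }
  mean(image$voxels[voi$indices]) * voi$volume_ml
}

#' Pooled background statistics over one or more VOIs
#'
#' Voxel values from all background VOIs are pooled; the mean and the sample
#' standard deviation (denominator n - 1) of the pooled values are returned.
#'
#' @param image An [activity_image()].
#' @param background_vois A list of [make_voi()] objects.
#' @return A tibble of class `background_estimate` with `mu_b`, `sigma_b`
#'   and `n_voxels`.
#' @export
background_stats <- function(image, background_vois) {
  if (inherits(background_vois, "voi")) background_vois <- list(background_vois)
  if (length(background_vois) < 1L) {
    stop("at least one background VOI is required", call. = FALSE)
  }
  vals <- unlist(lapply(background_vois, function(v) image$voxels[v$indices]))
  if (length(vals) < 2L) {
    stop("need at least 2 background voxels (degenerate statistics)", call. = FALSE)
  }
  out <- tibble::tibble(
    mu_b = mean(vals), sigma_b = stats::sd(vals), n_voxels = length(vals)
  )
  class(out) <- c("background_estimate", class(out))
  out
}

#' Contrast-to-noise ratio of a well
#'
#' The detectability statistic `CNR = (mu_well - mu_background) /
#' sigma_background`, where the mus are mean activity concentrations over
#' the well and background VOIs and sigma is the SD of background voxel
#' values. Negative values are retained unless `clip_at_zero = TRUE`.
#'
#' @param mu_well Mean well concentration, kBq/mL (vectorized).
#' @param mu_background Mean background concentration, kBq/mL.
#' @param sigma_background SD of background voxel values, kBq/mL; must be
#'   positive.
#' @param clip_at_zero Clip negative CNRs to 0 (off by default).
#' @return Dimensionless CNR.
#' @export
#' @examples
#' cnr(12, 2, 5) # 2
cnr <- function(mu_well, mu_background, sigma_background, clip_at_zero = FALSE) {
  if (any(!is.finite(sigma_background)) || any(sigma_background <= 0)) {
    stop("sigma_background must be positive (undefined CNR)", call. = FALSE)
  }
  out <- (mu_well - mu_background) / sigma_background
  if (clip_at_zero) out <- pmax(out, 0)
  out
}

# VOIs for the loaded wells and background regions of a plate.
plate_vois <- function(image, plate, height_margin = 6) {
  sh <- attr(plate, "shape")
  lay <- attr(plate, "layout")
  if (sh$type == "cylinder") {
    mk <- function(x, y, z) {
      make_voi(image, "cylinder", center = c(x, y, z),
               diameter = sh$diameter, height = sh$height + height_margin)
    }
    wells <- lapply(seq_len(nrow(plate)), function(i) {
      mk(plate$x[i], plate$y[i], plate$z[i])
    })
    # background: the unoccupied layout positions (empty wells)
    pos <- plate_layout(lay)$positions
    empty <- pos[-seq_len(nrow(plate)), , drop = FALSE]
    if (nrow(empty) == 0L) {
      stop("no empty well positions available for background VOIs", call. = FALSE)
    }
    bg <- lapply(seq_len(nrow(empty)), function(i) {
      mk(empty$x[i], empty$y[i], empty$z[i])
    })
  } else {
    mk <- function(x, y, z) make_voi(image, "cube", center = c(x, y, z), edge = sh$edge)
    wells <- lapply(seq_len(nrow(plate)), function(i) {
      mk(plate$x[i], plate$y[i], plate$z[i])
    })
    bgpos <- attr(plate, "background")
    bg <- lapply(seq_len(nrow(bgpos)), function(i) {
      mk(bgpos$x[i], bgpos$y[i], bgpos$z[i])
    })
  }
  list(wells = wells, background = bg)
}

#' Quantify every well of a plate on an image
#'
#' Places one VOI per loaded well (cylindrical VOIs of the well diameter and
#' the fill height plus a blur margin for 6-well plates; 1 cm^3 cubes for the
#' cubic plate), auto-places background VOIs at the empty well positions
#' (6-well) or between the well grid and the case (cubic plate), and returns
#' per-well total image activity, mean concentrations and CNR.
#'
#' @param image An [activity_image()] (a simulated or measured scan).
#' @param plate The [plate_spec()] describing the plate on this image.
#' @param height_margin Extra cylinder height beyond the fill height, mm
#'   (default 6, about one PSF FWHM), standing in for selecting all
#'   contiguous slices that contain the activity distribution.
#' @param clip_cnr_at_zero Clip negative CNRs to 0 (off by default).
#'
#' @return A tibble with one row per loaded well: `well_id`, `image_kBq`,
#'   `mu_w`, `mu_b`, `sigma_b`, `cnr`, `voi_volume_ml`, `background_kBq`
#'   (mean background concentration times the well-VOI volume). The plate
#'   background estimate is attached as attribute `"background"`.
#' @export
quantify_plate <- function(image, plate, height_margin = 6,
                           clip_cnr_at_zero = FALSE) {
  stopifnot(inherits(image, "activity_image"), inherits(plate, "plate_spec"))
  if (nrow(plate) == 0L) {
    out <- tibble::tibble(
      well_id = character(), image_kBq = numeric(), mu_w = numeric(),
      mu_b = numeric(), sigma_b = numeric(), cnr = numeric(),
      voi_volume_ml = numeric(), background_kBq = numeric()
    )
    return(out)
  }
  vois <- plate_vois(image, plate, height_margin)
  bg <- background_stats(image, vois$background)
  act <- vapply(vois$wells, function(v) voi_total_activity(image, v), 0)
  vol <- vapply(vois$wells, `[[`, 0, "volume_ml")
  mu_w <- act / vol
  # a perfectly flat background (sigma = 0) leaves CNR undefined; report NA
  # instead of failing so that noiseless phantoms can still be quantified
  cnr_val <- if (bg$sigma_b > 0) {
    cnr(mu_w, bg$mu_b, bg$sigma_b, clip_at_zero = clip_cnr_at_zero)
  } else {
    rep(NA_real_, length(mu_w))
  }
  out <- tibble::tibble(
    well_id = plate$well_id,
    image_kBq = act,
    mu_w = mu_w,
    mu_b = bg$mu_b,
    sigma_b = bg$sigma_b,
    cnr = cnr_val,
    voi_volume_ml = vol,
    background_kBq = bg$mu_b * vol
  )
  attr(out, "background") <- bg
  out
}

#' Quantify all scans of a generated study
#'
#' Runs [quantify_plate()] on every (plate, scanner) image of a
#' [generate_study()] result and joins the per-well ground truth and counter
#' measurements, yielding the study-level well table that all downstream
#' analyses (LLD, detection probability, recovery) consume.
#'
#' @param study A `pet_study` from [generate_study()].
#' @param ... Passed to [quantify_plate()].
#' @return A tibble with one row per (well, scanner): design columns
#'   (`plate_id`, `scanner`, `layout`, `experiment`, `cell_number`,
#'   `specific_activity`, `cell_density`, `truth_kBq`, `counter_kBq`,
#'   `qc_excluded`, `seed`) plus measurement columns from [quantify_plate()]
#'   and `mu_signal = mu_w - mu_b`.
#' @export
quantify_study <- function(study, ...) {
  stopifnot(inherits(study, "pet_study"))
  rows <- list()
  for (pid in names(study$plates)) {
    plate <- study$plates[[pid]]
    for (sid in names(study$scans[[pid]])) {
      q <- quantify_plate(study$scans[[pid]][[sid]], plate, ...)
      q$plate_id <- pid
      q$scanner <- sid
      rows[[paste(pid, sid)]] <- q
    }
  }
  meas <- dplyr::bind_rows(rows)
  out <- dplyr::inner_join(study$counter, meas, by = c("plate_id", "well_id"))
  out$mu_signal <- out$mu_w - out$mu_b
  dplyr::relocate(out, "plate_id", "scanner", "layout", "well_id")
}
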