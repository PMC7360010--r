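#' Scanner model for image formation
#'
#' A deliberately minimal description of a PET system as seen by the
#' downstream detectability analysis: an isotropic Gaussian point-spread
#' function, a uniform non-specific background inside the plate support, and
#' Poisson counting noise whose variance is proportional to the local mean —
#' the only noise property the detection analysis relies on. It does not
#' model acquisition or reconstruction of any particular scanner.
#'
#' @param scanner_id `"petct"` or `"petmri"`.
#' @param psf_fwhm Full width at half maximum of the Gaussian PSF, mm.
#' @param sensitivity_scale Dimensionless calibration from reconstructed
#'   counts back to kBq/mL (1 = perfectly calibrated).
#' @param background_concentration Uniform background added inside the plate
#'   support, kBq/mL.
#' @param noise_scale Expected counts per (kBq/mL) per voxel; governs the
#'   Poisson noise level. `Inf` disables noise.
#'
#' @return An object of class `scanner_model`.
#' @export
scanner_model <- function(scanner_id = c("petct", "petmri"),
                          psf_fwhm = 6,
                          sensitivity_scale = 1,
                          background_concentration = 0,
                          noise_scale = Inf) {
  scanner_id <- match.arg(scanner_id)
  if (psf_fwhm < 0) stop("psf_fwhm must be >= 0", call. = FALSE)
  if (!(noise_scale > 0)) stop("noise_scale must be > 0", call. = FALSE)
  if (background_concentration < 0) {
    stop("background_concentration must be >= 0", call. = FALSE)
  }
  structure(
    list(
      scanner_id = scanner_id, psf_fwhm = psf_fwhm,
      sensitivity_scale = sensitivity_scale,
      background_concentration = background_concentration,
      noise_scale = noise_scale
    ),
    class = "scanner_model"
  )
}

#' Simulate a scan of a ground-truth activity image
#'
#' Image formation is (1) Gaussian blur with the scanner PSF, applied in
#' continuous kBq/mL space; (2) addition of the uniform background
#' concentration inside the plate support region (zero outside, mimicking
#' air around the plate); (3) conversion to expected counts per voxel via
#' `noise_scale`, a Poisson draw, and conversion back to kBq/mL via
#' `sensitivity_scale`. The blur kernel is column-normalized, so total
#' activity is conserved up to edge truncation (< 0.1% with padding of at
#' least 3 FWHM). The same seed always yields the identical image.
#'
#' @param truth An [activity_image()], e.g. from [rasterize_truth()].
#' @param scanner A [scanner_model()].
#' @param seed Integer seed; required whenever noise is enabled.
#'
#' @return An [activity_image()] of the simulated scan.
#' @export
simulate_scan <- function(truth, scanner, seed = NULL) {
  stopifnot(inherits(truth, "activity_image"), inherits(scanner, "scanner_model"))
  noisy <- is.finite(scanner$noise_scale)
  if (noisy && is.null(seed)) {
    stop("a seed is required when Poisson noise is enabled (reproducibility)",
      call. = FALSE
    )
  }
  v <- blur_gaussian(truth$voxels, scanner$psf_fwhm, truth$voxel_size)
  if (scanner$background_concentration > 0) {
    mask <- support_mask(truth)
    v[mask] <- v[mask] + scanner$background_concentration
  }
  if (noisy) {
    lambda <- pmax(v, 0) * scanner$noise_scale
    counts <- withr::with_seed(as.integer(seed), {
      stats::rpois(length(lambda), lambda)
    })
    v <- array(counts / scanner$noise_scale * scanner$sensitivity_scale, dim(v))
  } else {
    v <- v * scanner$sensitivity_scale
  }
  out <- activity_image(v, truth$voxel_size, truth$origin)
  attr(out, "support") <- attr(truth, "support")
  out
}

# Logical mask of voxels inside the plate support box (whole image if the
# truth image carries no support attribute).
support_mask <- function(image) {
  sup <- attr(image, "support")
  if (is.null(sup)) return(array(TRUE, dim(image$voxels)))
  inside <- lapply(1:3, function(ax) {
    co <- axis_coords(image, ax)
    co >= sup$lo[ax] & co <= sup$hi[ax]
  })
  outer(outer(inside[[1]], inside[[2]], `&`), inside[[3]], `&`)
}

# Separable Gaussian blur with a truncated, renormalized discrete kernel.
# Column sums of the kernel matrix are exactly 1 away from the array edge,
# so activity is conserved for sources further than the truncation radius
# from the boundary.
blur_gaussian <- function(v, fwhm_mm, voxel_size) {
  if (fwhm_mm <= 0) return(v)
  sig <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size
  for (ax in 1:3) v <- conv_axis(v, ax, sig[ax])
  v
}

conv_axis <- function(v, ax, s) {
  if (s <= 0) return(v)
  n <- dim(v)[ax]
  r <- as.integer(ceiling(3.5 * s))
  off <- -r:r
  w <- exp(-off^2 / (2 * s^2))
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (j in seq_len(n)) {
    i <- j + off
    ok <- i >= 1L & i <= n
    K[cbind(i[ok], j)] <- w[ok]
  }
  perm <- c(ax, setdiff(1:3, ax))
  vp <- aperm(v, perm)
  d <- dim(vp)
  m <- K %*% matrix(vp, d[1])
  dim(m) <- d
  aperm(m, order(perm))
}
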