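#' Default loading of the 3 x 3 cubic-well plate
#'
#' Nine 1 cm^3 wells spanning roughly three decades of cell number and two
#' decades of specific activity, the reference loading pattern used to probe
#' how cell density and per-cell label loading drive recovery.
#'
#' @return A tibble with `well_id`, `cell_number` and `specific_activity`
#'   (kBq per 10^6 cells).
#' @export
cubic_plate_default_wells <- function() {
  tibble::tibble(
    well_id = c("L1", "L2", "L3", "M1", "M2", "M3", "H1", "H2", "H3"),
    cell_number = c(1.07e6, 1.50e5, 6.70e4, 8.20e5, 3.25e4, 3.61e4,
                    3.99e5, 1.21e5, 6.20e4),
    specific_activity = c(0.67, 0.42, 0.14, 7.23, 15.41, 6.61,
                          30.63, 8.47, 6.60)
  )
}

#' Study design configuration
#'
#' Describes a full in vitro detection-limit study: repeated 6-well plates
#' loaded at three nominal cell levels with log-uniform specific activities,
#' scanned by two scanner models, plus one 3 x 3 cubic-well plate, with a
#' fixed number of wells flagged for quality-control exclusion.
#'
#' The defaults emulate the study design this analysis targets: 6
#' independent experiments contributing 12 six-well plates (36 loaded wells)
#' per scanner arm with nominal cell levels whose medians sit near
#' 1.08e6 / 1.45e5 / 8.5e4 cells, specific activities log-uniform on
#' 0.43-31.91 kBq per 10^6 cells, and 5 wells excluded by QC.
#'
#' @param n_experiments Number of independent experiments.
#' @param plates_per_arm Number of 6-well plates (each scanned on both
#'   scanners).
#' @param wells_per_plate Loaded wells per 6-well plate (the remaining
#'   positions stay empty and provide the background VOIs).
#' @param cell_levels Median cell numbers of the nominal loading levels.
#' @param cell_jitter_sdlog SD of the log-normal jitter around each level.
#' @param sa_range Specific-activity range, kBq per 10^6 cells (log-uniform).
#' @param n_excluded Number of wells flagged `qc_excluded` per study.
#' @param counter_cv Relative SD of the well-counter measurement.
#' @param voxel_size Image voxel edge, mm.
#' @param padding Image grid margin around the plate frame, mm.
#' @param scanners List of two [scanner_model()] objects.
#' @param include_cubic Whether to include the 3 x 3 cubic-well plate.
#' @param cubic_wells Loading of the cubic plate (see
#'   [cubic_plate_default_wells()]).
#' @param seed Integer master seed for all randomness.
#'
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_experiments = 6L,
                         plates_per_arm = 12L,
                         wells_per_plate = 3L,
                         cell_levels = c(1.08e6, 1.45e5, 8.50e4),
                         cell_jitter_sdlog = 0.75,
                         sa_range = c(0.43, 31.91),
                         n_excluded = 5L,
                         counter_cv = 0.02,
                         voxel_size = 1,
                         padding = 18,
                         scanners = list(
                           scanner_model("petct", psf_fwhm = 6,
                                         background_concentration = 0.002,
                                         noise_scale = 1000),
                           scanner_model("petmri", psf_fwhm = 5,
                                         background_concentration = 0.002,
                                         noise_scale = 1000)
                         ),
                         include_cubic = TRUE,
                         cubic_wells = cubic_plate_default_wells(),
                         seed = 1L) {
  if (plates_per_arm < 1L) stop("need at least one plate", call. = FALSE)
  if (wells_per_plate < 1L || wells_per_plate > 6L) {
    stop("wells_per_plate must be in 1..6", call. = FALSE)
  }
  if (any(sa_range < 0) || length(sa_range) != 2L || sa_range[2] < sa_range[1]) {
    stop("sa_range must be an increasing non-negative interval", call. = FALSE)
  }
  if (n_excluded >= plates_per_arm * wells_per_plate) {
    stop("n_excluded must be smaller than the total number of wells", call. = FALSE)
  }
  if (length(cell_levels) != wells_per_plate) {
    stop("need one cell level per loaded well", call. = FALSE)
  }
  stopifnot(length(scanners) >= 1L, all(vapply(scanners, inherits, TRUE, "scanner_model")))
  structure(
    list(
      n_experiments = as.integer(n_experiments),
      plates_per_arm = as.integer(plates_per_arm),
      wells_per_plate = as.integer(wells_per_plate),
      cell_levels = cell_levels,
      cell_jitter_sdlog = cell_jitter_sdlog,
      sa_range = sa_range,
      n_excluded = as.integer(n_excluded),
      counter_cv = counter_cv,
      voxel_size = voxel_size,
      padding = padding,
      scanners = scanners,
      include_cubic = isTRUE(include_cubic),
      cubic_wells = tibble::as_tibble(cubic_wells),
      seed = as.integer(seed)
    ),
    class = "study_config"
  )
}

#' Generate a complete synthetic study
#'
#' Draws the cell loadings, builds the plates, rasterizes the ground truth,
#' simulates well-counter measurements and a scan of every plate on each
#' scanner, and flags the QC-excluded wells. All randomness descends from
#' `config$seed`, so the same configuration reproduces the study exactly.
#'
#' @param config A [study_config()].
#' @return An object of class `pet_study`: a list with `config`, `plates`
#'   (named list of [plate_spec()]), `counter` (per-well ground truth and
#'   counter measurements), and `scans` (`scans[[plate_id]][[scanner_id]]`
#'   [activity_image()] objects).
#' @export
generate_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  n_sub <- config$plates_per_arm * (2 + length(config$scanners)) + 10
  subseed <- withr::with_seed(config$seed, sample.int(2^31 - 2, n_sub))
  draw <- local({
    i <- 0L
    function() {
      i <<- i + 1L
      subseed[i]
    }
  })

  n_plates <- config$plates_per_arm
  plate_ids <- sprintf("P%02d", seq_len(n_plates))
  experiment <- rep(seq_len(config$n_experiments), length.out = n_plates)

  # QC flags: n_excluded of the loaded six-well wells, shared by both arms
  total_wells <- n_plates * config$wells_per_plate
  excl_idx <- withr::with_seed(draw(), sample.int(total_wells, config$n_excluded))

  plates <- list()
  scans <- list()
  counter <- list()
  widx <- 0L
  for (p in seq_len(n_plates)) {
    sds <- withr::with_seed(draw(), list(
      cells = stats::rlnorm(config$wells_per_plate,
                            meanlog = log(config$cell_levels),
                            sdlog = config$cell_jitter_sdlog),
      sa = if (config$sa_range[1] == config$sa_range[2]) {
        rep(config$sa_range[1], config$wells_per_plate)
      } else {
        exp(stats::runif(config$wells_per_plate,
                         log(config$sa_range[1]), log(config$sa_range[2])))
      }
    ))
    qc <- (widx + seq_len(config$wells_per_plate)) %in% excl_idx
    widx <- widx + config$wells_per_plate
    plate <- plate_spec("six_well", tibble::tibble(
      cell_number = sds$cells,
      specific_activity = sds$sa,
      qc_excluded = qc
    ))
    pid <- plate_ids[p]
    plates[[pid]] <- plate
    cnt <- simulate_well_counter(plate, config$counter_cv, seed = draw())
    cnt$plate_id <- pid
    cnt$experiment <- experiment[p]
    counter[[pid]] <- cnt
    truth <- rasterize_truth(plate, config$voxel_size, config$padding)
    scans[[pid]] <- lapply(config$scanners, function(sc) {
      simulate_scan(truth, sc, seed = draw())
    })
    names(scans[[pid]]) <- vapply(config$scanners, `[[`, "", "scanner_id")
  }

  if (config$include_cubic) {
    plate <- plate_spec("cubic_3x3", config$cubic_wells)
    pid <- "CUBE"
    plates[[pid]] <- plate
    cnt <- simulate_well_counter(plate, config$counter_cv, seed = draw())
    cnt$plate_id <- pid
    cnt$experiment <- NA_integer_
    counter[[pid]] <- cnt
    truth <- rasterize_truth(plate, config$voxel_size, config$padding)
    scans[[pid]] <- lapply(config$scanners, function(sc) {
      simulate_scan(truth, sc, seed = draw())
    })
    names(scans[[pid]]) <- vapply(config$scanners, `[[`, "", "scanner_id")
  }

  counter_tbl <- dplyr::bind_rows(lapply(names(plates), function(pid) {
    pl <- plates[[pid]]
    dplyr::left_join(
      counter[[pid]],
      tibble::tibble(
        well_id = pl$well_id,
        layout = attr(pl, "layout"),
        cell_number = pl$cell_number,
        specific_activity = pl$specific_activity,
        cell_density = pl$cell_density,
        qc_excluded = pl$qc_excluded
      ),
      by = "well_id"
    )
  }))
  counter_tbl$seed <- config$seed

  structure(
    list(config = config, plates = plates, counter = counter_tbl, scans = scans),
    class = "pet_study"
  )
}

#' @export
print.pet_study <- function(x, ...) {
  cat(
    "<pet_study> ", length(x$plates), " plates, ",
    nrow(x$counter), " wells, scanners: ",
    paste(vapply(x$config$scanners, `[[`, "", "scanner_id"), collapse = ", "),
    ", seed ", x$config$seed, "\n",
    sep = ""
  )
  invisible(x)
}
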