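WELL_TABLE_COLUMNS <- c(
  "well_id", "plate_id", "scanner", "layout", "cell_number",
  "specific_activity_kBq_per_1e6", "truth_kBq", "counter_kBq",
  "qc_excluded", "seed"
)

#' Write an activity image as NIfTI-1
#'
#' Voxel values are stored as-is (kBq/mL); the voxel size goes into the
#' header pixdim and the world origin into a diagonal qform, so
#' [read_activity_image()] round-trips the grid exactly.
#'
#' @param image An [activity_image()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_activity_image <- function(image, path) {
  stopifnot(inherits(image, "activity_image"))
  nii <- RNifti::asNifti(image$voxels)
  RNifti::pixdim(nii) <- image$voxel_size
  m <- diag(c(image$voxel_size, 1))
  m[1:3, 4] <- image$origin
  RNifti::qform(nii) <- structure(m, code = 2L)
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Read an activity image from NIfTI-1
#'
#' Accepts single-volume 3-D files only; voxel values are interpreted as
#' kBq/mL, the voxel size is taken from the header and the origin from the
#' qform offset.
#'
#' @param path A NIfTI-1 file.
#' @return An [activity_image()].
#' @export
read_activity_image <- function(path) {
  nii <- RNifti::readNifti(path)
  d <- dim(nii)
  if (length(d) == 4L && d[4] == 1L) {
    dim(nii) <- d[1:3]
    d <- d[1:3]
  }
  if (length(d) != 3L) {
    stop("expected a single 3-D volume, got ", length(d), "-D (format error)",
      call. = FALSE
    )
  }
  vs <- RNifti::pixdim(nii)[1:3]
  origin <- RNifti::xform(nii)[1:3, 4]
  activity_image(array(as.numeric(nii), d), voxel_size = vs, origin = origin)
}

#' Write a well-record table as CSV
#'
#' Fixed-header CSV with units encoded in column names (UTF-8, '.' decimal).
#' The internal `specific_activity` column is written as
#' `specific_activity_kBq_per_1e6`; measurement columns (`image_kBq`, `cnr`,
#' `mu_w`, `mu_b`, `sigma_b`, ...) are appended when present.
#'
#' @param wells A well-record data frame (e.g. from [quantify_study()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_well_table <- function(wells, path) {
  out <- tibble::as_tibble(wells)
  if ("specific_activity" %in% names(out)) {
    out <- dplyr::rename(out,
      specific_activity_kBq_per_1e6 = "specific_activity"
    )
  }
  missing_cols <- setdiff(WELL_TABLE_COLUMNS, names(out))
  for (m in missing_cols) out[[m]] <- NA
  extra <- setdiff(names(out), WELL_TABLE_COLUMNS)
  out <- out[c(WELL_TABLE_COLUMNS, extra)]
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a well-record table from CSV
#'
#' Validates the fixed schema written by [write_well_table()]; QC-excluded
#' rows are retained but flagged. The unit-suffixed specific-activity column
#' is mapped back to `specific_activity`.
#'
#' @param path CSV path.
#' @return A tibble of well records.
#' @export
read_well_table <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(WELL_TABLE_COLUMNS, names(tb))
  if (length(missing_cols)) {
    stop("well table is missing required column(s): ",
      paste(missing_cols, collapse = ", "), " (schema error)",
      call. = FALSE
    )
  }
  if (any(tb$cell_number < 0, na.rm = TRUE)) {
    stop("negative cell_number (validation error)", call. = FALSE)
  }
  tb <- dplyr::rename(tb, specific_activity = "specific_activity_kBq_per_1e6")
  tb$qc_excluded <- as.logical(tb$qc_excluded)
  tb
}

#' Read a study configuration from YAML
#'
#' Top-level YAML keys map to [study_config()] arguments; scanners are
#' given as a list of mappings with [scanner_model()] fields.
#'
#' @param path YAML file.
#' @return A [study_config()].
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$scanners)) {
    y$scanners <- lapply(y$scanners, function(s) do.call(scanner_model, s))
  }
  if (!is.null(y$cubic_wells)) {
    y$cubic_wells <- tibble::as_tibble(y$cubic_wells)
  }
  known <- names(formals(study_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  do.call(study_config, y)
}

write_report_json <- function(x, path) {
  x$schema_version <- "1.0"
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> quantify -> lld -> detprob -> rc -> agree on a study
#' configuration, writing every intermediate artifact (well table CSV, JSON
#' fit reports, optionally NIfTI images) under `out_dir` together with a
#' provenance manifest. Rerunning with the same configuration and seed
#' reproduces the tables and reports bit-identically.
#'
#' @param config A [study_config()].
#' @param out_dir Output directory (created if needed).
#' @param write_images Also write each simulated scan as NIfTI (off by
#'   default; the images are bulky and fully reproducible from the seed).
#' @return The manifest: a tibble with one row per stage (`stage`,
#'   `outputs`, `seed`, `elapsed_s`), invisibly writing `manifest.json`.
#' @export
run_pipeline <- function(config = study_config(), out_dir, write_images = FALSE) {
  stopifnot(inherits(config, "study_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  tick <- function(stage, outputs, t0) {
    stages[[stage]] <<- tibble::tibble(
      stage = stage, outputs = paste(outputs, collapse = ";"),
      seed = config$seed, elapsed_s = round(as.numeric(Sys.time()) - t0, 3)
    )
  }

  t0 <- as.numeric(Sys.time())
  study <- generate_study(config)
  outs <- character()
  if (write_images) {
    for (pid in names(study$scans)) {
      for (sid in names(study$scans[[pid]])) {
        f <- file.path(out_dir, sprintf("%s_%s.nii.gz", pid, sid))
        write_activity_image(study$scans[[pid]][[sid]], f)
        outs <- c(outs, f)
      }
    }
  }
  tick("simulate", outs, t0)

  t0 <- as.numeric(Sys.time())
  wells <- quantify_study(study)
  f_wells <- file.path(out_dir, "wells.csv")
  write_well_table(wells, f_wells)
  tick("quantify", f_wells, t0)

  six <- dplyr::filter(wells, .data$layout == "six_well")
  arms <- sort(unique(six$scanner))

  t0 <- as.numeric(Sys.time())
  lld <- lapply(arms, function(a) {
    res <- estimate_lld(dplyr::filter(six, .data$scanner == a))
    rose <- estimate_lld(dplyr::filter(six, .data$scanner == a), rule = "rose")
    list(
      scanner = a, rule = res$rule, cnr_threshold = res$cnr_threshold,
      lld_cells = res$lld_cells,
      lld_specific_activity = res$lld_specific_activity,
      rose_lld_cells = rose$lld_cells,
      rose_lld_specific_activity = rose$lld_specific_activity, n = res$n
    )
  })
  f_lld <- file.path(out_dir, "lld.json")
  write_report_json(list(results = lld), f_lld)
  tick("lld", f_lld, t0)

  t0 <- as.numeric(Sys.time())
  detprob <- lapply(arms, function(a) {
    d <- dplyr::filter(six, .data$scanner == a)
    k <- estimate_poisson_k(d)
    bg <- simulate_background_levels(d, k = k)
    dv <- detection_vs_background(bg)
    list(
      scanner = a, k = k, n_datasets = nrow(bg),
      fractions = dv$fraction, beta0 = dv$beta0, beta1 = dv$beta1,
      inestimable = dv$inestimable, cells_at_p90 = dv$cells_at_p
    )
  })
  f_det <- file.path(out_dir, "detprob.json")
  write_report_json(list(results = detprob), f_det)
  tick("detprob", f_det, t0)

  t0 <- as.numeric(Sys.time())
  cub <- dplyr::filter(wells, .data$layout == "cubic_3x3")
  f_rc <- file.path(out_dir, "rcfit.json")
  if (nrow(cub) >= 6L) {
    cub <- dplyr::mutate(cub, rc = recovery_coefficient(
      .data$image_kBq, .data$background_kBq, .data$counter_kBq
    ))
    rcf <- fit_rc_model(cub)
    write_report_json(list(
      slope = rcf$slope, intercept = rcf$intercept,
      ranef = as.list(rcf$ranef), sigma = rcf$sigma,
      n = rcf$n, method = rcf$method
    ), f_rc)
  } else {
    write_report_json(list(skipped = "no cubic plate in study"), f_rc)
  }
  tick("rc", f_rc, t0)

  t0 <- as.numeric(Sys.time())
  f_agree <- file.path(out_dir, "agree.json")
  if (length(arms) >= 2L) {
    wide <- tidyr::pivot_wider(
      dplyr::select(six, "plate_id", "well_id", "scanner", "image_kBq", "cnr"),
      names_from = "scanner", values_from = c("image_kBq", "cnr")
    )
    ba_act <- bland_altman(wide, !!rlang::sym(paste0("image_kBq_", arms[1])),
                           !!rlang::sym(paste0("image_kBq_", arms[2])))
    ba_cnr <- bland_altman(wide, !!rlang::sym(paste0("cnr_", arms[1])),
                           !!rlang::sym(paste0("cnr_", arms[2])))
    cors <- lapply(arms, function(a) {
      d <- dplyr::filter(six, .data$scanner == a, !.data$qc_excluded)
      c(list(scanner = a), as.list(pearson(d, .data$counter_kBq, .data$image_kBq)))
    })
    write_report_json(list(
      activity = as.list(ba_act[1, ]), cnr = as.list(ba_cnr[1, ]),
      pearson_image_vs_counter = cors
    ), f_agree)
  } else {
    write_report_json(list(skipped = "fewer than two scanner arms"), f_agree)
  }
  tick("agree", f_agree, t0)

  manifest <- dplyr::bind_rows(stages)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest
}
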