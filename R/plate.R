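#' Plate layout geometry
#'
#' Two layouts are supported, mirroring the two phantom geometries used for
#' detection-limit work with radiolabeled cell suspensions:
#'
#' * `six_well`: a standard 6-well culture plate (128 x 85 mm footprint) with
#'   cylindrical wells of 34 mm diameter holding a 5 mm deep cell suspension.
#' * `cubic_3x3`: a 3 x 3 grid of 1 cm^3 cubic wells (10 mm edge) inside a
#'   62 x 62 mm case, used to probe the effect of cell density.
#'
#' Background region positions (empty wells for `six_well`, the gap between
#' the well grid and the case for `cubic_3x3`) are part of the layout.
#'
#' @param layout `"six_well"` or `"cubic_3x3"`.
#' @return A list with well positions, shapes, capacity, plate frame (mm
#'   bounding box) and background-region positions.
#' @export
plate_layout <- function(layout = c("six_well", "cubic_3x3")) {
  layout <- match.arg(layout)
  if (layout == "six_well") {
    xs <- c(25, 64, 103)
    ys <- c(62, 23)
    pos <- tibble::tibble(
      position = 1:6,
      well_id = c("A1", "A2", "A3", "B1", "B2", "B3"),
      x = rep(xs, 2),
      y = rep(ys, each = 3),
      z = 2.5
    )
    list(
      layout = layout,
      capacity = 6L,
      positions = pos,
      shape = list(type = "cylinder", diameter = 34, height = 5),
      frame = list(lo = c(0, 0, 0), hi = c(128, 85, 5)),
      # background VOIs default to unoccupied well positions
      background = NULL
    )
  } else {
    g <- c(15, 30, 45)
    pos <- tibble::tibble(
      position = 1:9,
      well_id = paste0(rep(c("L", "M", "H"), each = 3), rep(1:3, 3)),
      x = rep(g, 3),
      y = rep(c(45, 30, 15), each = 3),
      z = 5
    )
    bg <- tibble::tibble(
      well_id = paste0("BG", 1:3),
      x = 56, y = g, z = 5
    )
    list(
      layout = layout,
      capacity = 9L,
      positions = pos,
      shape = list(type = "cube", edge = 10),
      frame = list(lo = c(0, 0, 0), hi = c(62, 62, 10)),
      background = bg
    )
  }
}

#' Build a plate specification
#'
#' Places wells with given cell loadings at the fixed layout coordinates and
#' records the derived ground-truth activity of each well,
#' `truth_kBq = cell_number * specific_activity / 1e6`. For cubic wells the
#' cell density (10^6 cells/mL) follows from the 1 mL well volume; for
#' cylindrical wells it is derived from the suspension volume.
#'
#' @param layout `"six_well"` or `"cubic_3x3"`.
#' @param wells Data frame with one row per loaded well: `cell_number`,
#'   `specific_activity` (kBq per 10^6 cells) and optionally `well_id` and
#'   `qc_excluded`.
#'
#' @return A tibble of class `plate_spec` with one row per loaded well
#'   (coordinates, shape parameters, `truth_kBq`, `cell_density`) and the
#'   layout stored as attributes.
#' @export
#' @examples
#' p <- plate_spec("six_well",
#'   tibble::tibble(cell_number = 1e6, specific_activity = 10))
#' p$truth_kBq # 10 kBq
plate_spec <- function(layout = c("six_well", "cubic_3x3"), wells) {
  layout <- match.arg(layout)
  lay <- plate_layout(layout)
  wells <- tibble::as_tibble(wells)
  if (!all(c("cell_number", "specific_activity") %in% names(wells))) {
    stop("`wells` needs columns cell_number and specific_activity", call. = FALSE)
  }
  if (nrow(wells) > lay$capacity) {
    stop(
      "too many wells for layout ", layout, ": ", nrow(wells), " > ",
      lay$capacity, " (capacity error)", call. = FALSE
    )
  }
  if (any(wells$cell_number < 0) || any(wells$specific_activity < 0)) {
    stop("cell_number and specific_activity must be non-negative", call. = FALSE)
  }
  n <- nrow(wells)
  pos <- lay$positions[seq_len(n), ]
  out <- tibble::tibble(
    well_id = if ("well_id" %in% names(wells)) wells$well_id else pos$well_id,
    x = pos$x, y = pos$y, z = pos$z,
    cell_number = as.numeric(wells$cell_number),
    specific_activity = as.numeric(wells$specific_activity),
    truth_kBq = as.numeric(wells$cell_number) * as.numeric(wells$specific_activity) / 1e6,
    qc_excluded = if ("qc_excluded" %in% names(wells)) wells$qc_excluded else FALSE
  )
  vol_ml <- if (lay$shape$type == "cube") {
    lay$shape$edge^3 / 1000
  } else {
    pi * (lay$shape$diameter / 2)^2 * lay$shape$height / 1000
  }
  out$cell_density <- out$cell_number / (1e6 * vol_ml)
  structure(out,
    class = c("plate_spec", class(out)),
    layout = layout, shape = lay$shape, frame = lay$frame,
    background = lay$background, capacity = lay$capacity,
    well_volume_ml = vol_ml
  )
}

well_shape <- function(plate, row) {
  sh <- attr(plate, "shape")
  sh$center <- c(plate$x[row], plate$y[row], plate$z[row])
  sh
}
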