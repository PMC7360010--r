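#' 3-D activity concentration image
#'
#' Container for a voxelized activity concentration map in kBq/mL, the unit
#' a calibrated PET reconstruction reports. World coordinates are in mm and
#' refer to voxel centers: voxel `(i, j, k)` (1-based) sits at
#' `origin + (c(i, j, k) - 1) * voxel_size`.
#'
#' @param voxels 3-D numeric array of activity concentrations (kBq/mL).
#' @param voxel_size Voxel edge lengths in mm (length 1 or 3).
#' @param origin World coordinate (mm) of the center of voxel `(1, 1, 1)`.
#'
#' @return An object of class `activity_image`.
#' @export
#' @examples
#' img <- activity_image(array(0, c(10, 10, 10)))
#' total_activity(img)
activity_image <- function(voxels, voxel_size = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop("`voxels` must be a 3-D array", call. = FALSE)
  }
  if (any(dim(voxels) < 1L)) stop("all image dimensions must be >= 1", call. = FALSE)
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
    stop("`voxel_size` must be positive and finite", call. = FALSE)
  }
  if (!all(is.finite(voxels))) {
    stop("concentration values must be finite", call. = FALSE)
  }
  structure(
    list(
      voxels = voxels,
      voxel_size = voxel_size,
      origin = rep_len(as.numeric(origin), 3L)
    ),
    class = "activity_image"
  )
}

#' @export
print.activity_image <- function(x, ...) {
  cat(
    "<activity_image> ", paste(dim(x$voxels), collapse = " x "),
    " voxels, ", paste(signif(x$voxel_size, 3), collapse = " x "),
    " mm; total ", signif(total_activity(x), 4), " kBq\n",
    sep = ""
  )
  invisible(x)
}

#' Voxel volume of an activity image
#'
#' @param image An [activity_image()].
#' @return Voxel volume in mL.
#' @export
voxel_volume_ml <- function(image) {
  prod(image$voxel_size) / 1000
}

#' Total activity in an image
#'
#' Sum of all voxel concentrations times the voxel volume.
#'
#' @param image An [activity_image()].
#' @return Total activity in kBq.
#' @export
total_activity <- function(image) {
  sum(image$voxels) * voxel_volume_ml(image)
}

# World coordinates of voxel centers along one axis.
axis_coords <- function(image, axis) {
  image$origin[axis] + (seq_len(dim(image$voxels)[axis]) - 1) * image$voxel_size[axis]
}

# Linear voxel indices whose centers fall inside a shape. Shapes are lists:
#   list(type = "cylinder", center, diameter, height, axis = 3)
#   list(type = "cube", center, edge)
# Membership: axial/cube extents are half-open [lo, hi) so a shape whose
# faces land on voxel-center planes still covers edge/voxel_size voxels per
# axis; the circular cross-section uses a strict `<` on the squared radius.
shape_voxel_indices <- function(image, shape) {
  dims <- dim(image$voxels)
  cx <- shape$center
  if (shape$type == "cube") {
    half <- shape$edge / 2
    inside <- lapply(1:3, function(ax) {
      co <- axis_coords(image, ax)
      co >= cx[ax] - half & co < cx[ax] + half
    })
    mask2d <- outer(inside[[1]], inside[[2]], `&`)
    zin <- inside[[3]]
  } else if (shape$type == "cylinder") {
    ax_long <- if (is.null(shape$axis)) 3L else as.integer(shape$axis)
    plane <- setdiff(1:3, ax_long)
    if (ax_long != 3L) stop("only plate-normal (z) cylinder axis is supported", call. = FALSE)
    d1 <- (axis_coords(image, plane[1]) - cx[plane[1]])^2
    d2 <- (axis_coords(image, plane[2]) - cx[plane[2]])^2
    mask2d <- outer(d1, d2, `+`) < (shape$diameter / 2)^2
    zco <- axis_coords(image, ax_long)
    zin <- zco >= cx[ax_long] - shape$height / 2 & zco < cx[ax_long] + shape$height / 2
  } else {
    stop("unknown shape type: ", shape$type, call. = FALSE)
  }
  lin2d <- which(mask2d)
  zidx <- which(zin)
  if (length(lin2d) == 0L || length(zidx) == 0L) return(integer(0))
  nxy <- dims[1] * dims[2]
  as.vector(outer(lin2d, (zidx - 1L) * nxy, `+`))
}
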