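#' Regular image grid shared by all volumes
#'
#' Defines the voxel lattice every mask, ADC map, and dose grid in an
#' analysis must share. The array axes are stored in a fixed anatomical
#' order: axis 1 craniocaudal (increasing index = more caudal), axis 2
#' anteroposterior, axis 3 transverse. Margin growing and distance
#' computations rely on this convention. No resampling is ever performed:
#' combining volumes on unequal grids is an error.
#'
#' @param shape integer vector of length 3, voxel counts per axis.
#' @param spacing numeric length 3, voxel size in mm per axis (all > 0).
#' @param origin numeric length 3, mm offset of the first voxel center.
#' @return An object of class \code{image_grid}.
#' @export
image_grid <- function(shape, spacing, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(shape) != 3L || any(shape < 1L))
    stop("shape must be three positive voxel counts")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive values in mm")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be three finite values in mm")
  structure(
    list(shape = shape, spacing = spacing, origin = origin,
         axis_labels = c("craniocaudal", "anteroposterior", "transverse")),
    class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> %s voxels @ %s mm (%s)\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              paste(substr(x$axis_labels, 1, 2), collapse = "/")))
  invisible(x)
}

#' Test two grids for equality
#'
#' Grids are equal when shapes match exactly and spacing and origin agree
#' within \code{tol} mm.
#'
#' @param a,b \code{image_grid} objects.
#' @param tol numeric tolerance in mm.
#' @return logical scalar.
#' @export
grids_equal <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    all(abs(a$spacing - b$spacing) <= tol) &&
    all(abs(a$origin - b$origin) <= tol)
}

check_same_grid <- function(a, b, what = "volumes") {
  if (!grids_equal(a$grid, b$grid))
    stop(sprintf("grid mismatch between %s: no implicit resampling is done",
                 what), call. = FALSE)
  invisible(TRUE)
}

#' Voxel volume in cubic millimetres
#' @param grid an \code{image_grid}.
#' @return numeric scalar, mm^3 per voxel.
#' @export
voxel_volume_mm3 <- function(grid) prod(grid$spacing)

# voxel-center coordinates (mm) along one axis
axis_coords <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$shape[axis]) - 1) * grid$spacing[axis]
}

# arrays of voxel-center coordinates in mm for all three axes
coord_arrays <- function(grid) {
  sh <- grid$shape
  list(
    cc = array(rep(axis_coords(grid, 1), times = sh[2] * sh[3]), dim = sh),
    ap = array(rep(rep(axis_coords(grid, 2), each = sh[1]), times = sh[3]),
               dim = sh),
    tr = array(rep(axis_coords(grid, 3), each = sh[1] * sh[2]), dim = sh))
}
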