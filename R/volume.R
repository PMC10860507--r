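#' Scalar volume on an image grid
#'
#' Container for voxelwise scalar data: dose in Gy (\code{dose_grid}) or an
#' apparent diffusion coefficient map in consistent arbitrary units
#' (\code{adc_map}). Values must be finite and nonnegative.
#'
#' @param values numeric array with dimensions equal to \code{grid$shape}.
#' @param grid an \code{\link{image_grid}}.
#' @return An object of class \code{dose_grid}/\code{adc_map} (both inherit
#'   \code{scalar_volume}).
#' @export
dose_grid <- function(values, grid) {
  scalar_volume(values, grid, "dose_grid")
}

#' @rdname dose_grid
#' @export
adc_map <- function(values, grid) {
  scalar_volume(values, grid, "adc_map")
}

scalar_volume <- function(values, grid, subclass) {
  if (!is.array(values) || !identical(dim(values), as.integer(grid$shape)))
    stop("values must be an array with dimensions equal to grid$shape")
  storage.mode(values) <- "double"
  if (anyNA(values) || any(!is.finite(values)))
    stop("values must be finite")
  if (any(values < 0)) stop("values must be nonnegative")
  structure(list(grid = grid, values = values),
            class = c(subclass, "scalar_volume"))
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, range [%.4g, %.4g]\n", class(x)[1],
              paste(x$grid$shape, collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Sum two dose grids voxelwise
#'
#' Physical-dose summation of two phases evaluated on one grid (biased-dose
#' combined plans). Grids must match exactly.
#'
#' @param a,b \code{dose_grid}s on the same grid.
#' @return \code{dose_grid}.
#' @export
sum_dose <- function(a, b) {
  check_same_grid(a, b, "dose grids")
  dose_grid(a$values + b$values, a$grid)
}
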