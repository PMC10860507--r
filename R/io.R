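# NIfTI input/output. Files are assumed to share one grid; the loader
# permutes file axes into the package's fixed internal anatomical order
# (craniocaudal, anteroposterior, transverse).

# default axis meaning of a NIfTI file laid out RAS-like:
# file axis 1 transverse (left-right), 2 anteroposterior, 3 craniocaudal
.default_file_axes <- c("transverse", "anteroposterior", "craniocaudal")

# permutation taking file axes to the internal (cc, ap, tr) order
axis_permutation <- function(file_axes) {
  want <- c("craniocaudal", "anteroposterior", "transverse")
  if (!setequal(file_axes, want))
    stop("file_axes must name craniocaudal, anteroposterior and transverse")
  match(want, file_axes)
}

read_nifti_array <- function(path, file_axes) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("expected a 3-D NIfTI volume: ", path)
  perm <- axis_permutation(file_axes)
  spacing <- RNifti::pixdim(img)[perm]
  list(values = aperm(arr, perm),
       grid = image_grid(dim(arr)[perm], spacing))
}

#' Read a structure mask or scalar volume from NIfTI
#'
#' \code{read_mask} reads a 0/1 structure volume; \code{read_dose} and
#' \code{read_adc} read scalar fields. \code{file_axes} states the
#' anatomical meaning of the file's array axes (default: transverse,
#' anteroposterior, craniocaudal, the common RAS-like layout); volumes are
#' permuted into the internal craniocaudal/anteroposterior/transverse
#' order on load.
#'
#' @param path path to a .nii or .nii.gz file.
#' @param file_axes character vector of length 3 naming the file axes.
#' @param name optional structure label for masks.
#' @return a \code{binary_mask}, \code{dose_grid} or \code{adc_map}.
#' @export
read_mask <- function(path, file_axes = .default_file_axes, name = NULL) {
  x <- read_nifti_array(path, file_axes)
  binary_mask(array(x$values != 0, dim = x$grid$shape), x$grid, name = name)
}

#' @rdname read_mask
#' @export
read_dose <- function(path, file_axes = .default_file_axes) {
  x <- read_nifti_array(path, file_axes)
  dose_grid(x$values, x$grid)
}

#' @rdname read_mask
#' @export
read_adc <- function(path, file_axes = .default_file_axes) {
  x <- read_nifti_array(path, file_axes)
  adc_map(x$values, x$grid)
}

#' Write a mask or scalar volume to NIfTI
#'
#' Masks are stored as 8-bit 0/1; scalar volumes as float32. Data are
#' permuted from the internal axis order back to \code{file_axes}.
#'
#' @param x a \code{binary_mask} or \code{scalar_volume}.
#' @param path output .nii or .nii.gz path.
#' @param file_axes axis meaning of the written file (see
#'   \code{\link{read_mask}}).
#' @return \code{path}, invisibly.
#' @export
write_nifti <- function(x, path, file_axes = .default_file_axes) {
  perm <- axis_permutation(file_axes)        # internal -> file needs inverse
  inv <- order(perm)
  if (inherits(x, "binary_mask")) {
    arr <- aperm(array(as.integer(x$voxels), dim = x$grid$shape), inv)
    datatype <- "uint8"
  } else if (inherits(x, "scalar_volume")) {
    arr <- aperm(x$values, inv)
    datatype <- "float"
  } else stop("x must be a binary_mask or scalar_volume")
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- x$grid$spacing[inv]
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}
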