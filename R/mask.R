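#' Binary structure mask on an image grid
#'
#' A voxelized structure (target volume or organ at risk). A voxel belongs
#' to the structure iff its center is inside; all geometry downstream uses
#' voxel-center distances.
#'
#' @param voxels logical array whose dimensions equal \code{grid$shape}.
#' @param grid an \code{\link{image_grid}}.
#' @param name optional structure label.
#' @return An object of class \code{binary_mask}.
#' @export
binary_mask <- function(voxels, grid, name = NULL) {
  if (!is.array(voxels) || !identical(dim(voxels), as.integer(grid$shape)))
    stop("voxels must be an array with dimensions equal to grid$shape")
  if (!is.logical(voxels)) {
    if (is.numeric(voxels)) voxels <- array(voxels != 0, dim = dim(voxels))
    else stop("voxels must be logical (or numeric 0/1)")
  }
  if (anyNA(voxels)) stop("mask voxels must not contain NA")
  structure(list(grid = grid, voxels = voxels, name = name),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s: %d voxels, %.2f cc\n",
              if (is.null(x$name)) "(unnamed)" else x$name,
              sum(x$voxels), volume_cc(x)))
  invisible(x)
}

#' Anisotropic margins for target expansion
#'
#' Margins are specified per anatomical direction in mm and applied as an
#' ellipsoidal structuring element (per-axis scaled Euclidean distance
#' at most 1), matching treatment-planning-system margin growing.
#'
#' @param anteroposterior,transverse,craniocaudal margins in mm, each >= 0.
#' @return An object of class \code{margins}.
#' @export
margins <- function(anteroposterior, transverse, craniocaudal) {
  m <- c(anteroposterior = as.numeric(anteroposterior),
         transverse = as.numeric(transverse),
         craniocaudal = as.numeric(craniocaudal))
  if (any(!is.finite(m)) || any(m < 0)) stop("margins must be finite and >= 0")
  structure(as.list(m), class = "margins")
}

# margins ordered to the internal axis convention (cc, ap, tr)
margins_by_axis <- function(m) {
  c(m$craniocaudal, m$anteroposterior, m$transverse)
}

#' Structure volume in cubic centimetres
#' @param mask a \code{binary_mask}.
#' @return volume in cc (voxel count times voxel volume / 1000).
#' @export
volume_cc <- function(mask) {
  sum(mask$voxels) * voxel_volume_mm3(mask$grid) / 1000
}

# exact Euclidean feature transform from the TRUE voxels of `voxels`
# given per-axis spacing; returns squared center distances and the linear
# index of the nearest source voxel
edt_transform <- function(voxels, spacing) {
  .edt_cpp(as.logical(voxels), as.integer(dim(voxels)), as.numeric(spacing))
}

#' Expand a mask by anisotropic margins
#'
#' Grows the structure with an ellipsoidal element: a voxel is included iff
#' some source voxel center u satisfies
#' (d_ap/m_ap)^2 + (d_tr/m_tr)^2 + (d_cc/m_cc)^2 <= 1, with center-to-center
#' distances in mm. A zero margin on an axis means no growth along that
#' axis. When \code{limit} is given the result is intersected with it.
#'
#' @param mask nonempty \code{binary_mask}.
#' @param m a \code{\link{margins}} object.
#' @param limit optional \code{binary_mask} on the same grid clipping the
#'   result.
#' @return expanded \code{binary_mask}.
#' @export
expand_mask <- function(mask, m, limit = NULL) {
  if (!sum(mask$voxels)) stop("cannot expand an empty mask: structure missing")
  if (!inherits(m, "margins")) stop("m must be a margins object")
  mm <- margins_by_axis(m)
  # zero margin => no growth on that axis: make cross-axis steps unreachable
  mm_eff <- ifelse(mm == 0, 1e-9, mm)
  scaled <- mask$grid$spacing / mm_eff
  ft <- edt_transform(mask$voxels, scaled)
  out <- array(ft$dist2 <= 1 + 1e-9, dim = mask$grid$shape)
  if (!is.null(limit)) {
    check_same_grid(mask, limit, "mask and limit")
    out <- out & limit$voxels
  }
  binary_mask(out, mask$grid, name = mask$name)
}

#' Shell of tissue beyond a distance from a structure
#'
#' Returns the voxels of \code{body}, outside \code{mask}, whose
#' center-to-nearest-mask-voxel-center Euclidean distance (anisotropic
#' spacing respected) is at least \code{distance_mm}.
#'
#' @param mask nonempty \code{binary_mask}.
#' @param distance_mm distance in mm (>= 0).
#' @param body \code{binary_mask} on the same grid.
#' @return \code{binary_mask} of the shell.
#' @export
shell_beyond <- function(mask, distance_mm, body) {
  if (!sum(mask$voxels)) stop("cannot take a shell around an empty mask")
  check_same_grid(mask, body, "mask and body")
  ft <- edt_transform(mask$voxels, mask$grid$spacing)
  far <- array(ft$dist2 >= distance_mm^2 - 1e-9, dim = mask$grid$shape)
  binary_mask(far & body$voxels & !mask$voxels, mask$grid)
}

#' Mask difference (a AND NOT b)
#' @param a,b \code{binary_mask}s on the same grid.
#' @return \code{binary_mask}.
#' @export
subtract_mask <- function(a, b) {
  check_same_grid(a, b, "masks")
  binary_mask(a$voxels & !b$voxels, a$grid, name = a$name)
}

#' Mask intersection
#' @param a,b \code{binary_mask}s on the same grid.
#' @return \code{binary_mask}.
#' @export
intersect_mask <- function(a, b) {
  check_same_grid(a, b, "masks")
  binary_mask(a$voxels & b$voxels, a$grid)
}

#' Mask union
#' @param a,b \code{binary_mask}s on the same grid.
#' @return \code{binary_mask}.
#' @export
union_mask <- function(a, b) {
  check_same_grid(a, b, "masks")
  binary_mask(a$voxels | b$voxels, a$grid)
}

#' Is mask a contained in mask b?
#' @param a,b \code{binary_mask}s on the same grid.
#' @return logical scalar.
#' @export
mask_subset <- function(a, b) {
  check_same_grid(a, b, "masks")
  !any(a$voxels & !b$voxels)
}

#' Keep only the largest 26-connected component
#'
#' Cleans non-contiguous voxels from a segmented structure: components are
#' labelled under 26-connectivity and only the largest is retained. A size
#' tie is broken in favour of the component whose centroid is most caudal
#' (largest mean index along the craniocaudal axis) and reported with a
#' message.
#'
#' @param mask nonempty \code{binary_mask}.
#' @return \code{binary_mask} holding the single retained component, with
#'   attribute \code{n_components} giving the original component count.
#' @export
clean_noncontiguous <- function(mask) {
  if (!sum(mask$voxels)) stop("cannot clean an empty mask")
  lab <- .label_components_cpp(as.logical(mask$voxels),
                               as.integer(mask$grid$shape))
  sizes <- tabulate(lab)
  biggest <- which(sizes == max(sizes))
  if (length(biggest) > 1L) {
    # tie: most caudal centroid wins
    cc_idx <- slice.index(array(0, dim = mask$grid$shape), 1)
    cents <- vapply(biggest, function(k) mean(cc_idx[lab == k]), numeric(1))
    message(sprintf(
      "component size tie (%d components of %d voxels): keeping most caudal",
      length(biggest), max(sizes)))
    biggest <- biggest[which.max(cents)]
  }
  out <- binary_mask(array(lab == biggest, dim = mask$grid$shape),
                     mask$grid, name = mask$name)
  attr(out, "n_components") <- length(sizes)
  out
}
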