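#' Cumulative dose-volume histogram
#'
#' Builds the cumulative DVH of a structure at fixed fine binning
#' (default 0.005 Gy = 0.5 cGy). \code{cum_volume_pct[k]} is the percent of
#' the structure receiving at least \code{bin_edges[k]}; edges run from 0
#' to the smallest bin multiple at or above the maximum structure dose.
#' Voxel-exact extremes (\code{dmin}, \code{dmax}, \code{dmean}) are kept
#' alongside so point metrics are not quantized by the binning.
#'
#' @param dose a \code{\link{dose_grid}}.
#' @param mask nonempty \code{binary_mask} on the same grid.
#' @param bin_width bin width in Gy (default 0.005).
#' @return object of class \code{dvh}.
#' @export
cumulative_dvh <- function(dose, mask, bin_width = 0.005) {
  if (!sum(mask$voxels)) stop("cannot build a DVH for an empty structure")
  if (!is.numeric(bin_width) || bin_width <= 0) stop("bin_width must be > 0")
  check_same_grid(dose, mask, "dose and structure")
  d <- sort(dose$values[mask$voxels])
  n <- length(d)
  nbins <- ceiling(max(d) / bin_width - 1e-9)
  edges <- (0:nbins) * bin_width
  # voxels strictly below each edge; cumulative volume is the complement
  n_below <- findInterval(edges, d, left.open = TRUE)
  cum_pct <- 100 * (n - n_below) / n
  structure(list(
    structure_name = if (is.null(mask$name)) "structure" else mask$name,
    bin_width = bin_width, bin_edges = edges, cum_volume_pct = cum_pct,
    total_volume_cc = volume_cc(mask),
    dmin = d[1], dmax = d[n], dmean = mean(d), n_voxels = n),
    class = "dvh")
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf(
    "<dvh> %s: %.2f cc, Dmin %.3f / Dmean %.3f / Dmax %.3f Gy, %d bins\n",
    x$structure_name, x$total_volume_cc, x$dmin, x$dmean, x$dmax,
    length(x$bin_edges)))
  invisible(x)
}

#' Dose covering a relative volume (Dx%)
#'
#' The largest dose d such that at least \code{pct} percent of the
#' structure receives d or more, with linear interpolation between the
#' bracketing DVH bin edges. D100% returns the exact minimum structure
#' dose.
#'
#' @param dvh a \code{\link{cumulative_dvh}} result.
#' @param pct percent of structure volume in (0, 100].
#' @return dose in Gy.
#' @export
dose_at_relative_volume <- function(dvh, pct) {
  if (!inherits(dvh, "dvh")) stop("dvh must be a dvh object")
  if (!is.numeric(pct) || pct <= 0 || pct > 100)
    stop("pct must lie in (0, 100]")
  if (pct == 100) return(dvh$dmin)
  cum <- dvh$cum_volume_pct
  i <- max(which(cum >= pct))          # cum[1] is 100, so i always exists
  if (i == length(cum)) return(dvh$bin_edges[i])
  dvh$bin_edges[i] +
    (cum[i] - pct) / (cum[i] - cum[i + 1]) * dvh$bin_width
}

#' Dose covering an absolute volume (DxCC)
#'
#' Dose to the hottest \code{cc} cubic centimetres, evaluated through the
#' relative-volume inverse of the DVH.
#'
#' @param dvh a \code{\link{cumulative_dvh}} result.
#' @param cc absolute volume in cc, 0 < cc <= structure volume.
#' @return dose in Gy.
#' @export
dose_at_absolute_volume <- function(dvh, cc) {
  if (!is.numeric(cc) || cc <= 0) stop("cc must be > 0")
  if (cc > dvh$total_volume_cc + 1e-9)
    stop("requested volume exceeds the structure volume")
  dose_at_relative_volume(dvh, min(100, 100 * cc / dvh$total_volume_cc))
}

#' Structure volume receiving at least a dose level (Vx)
#'
#' Computed directly from voxel values (not the binned DVH), with the
#' closed lower bound convention dose >= level.
#'
#' @param dose a \code{\link{dose_grid}}.
#' @param mask nonempty \code{binary_mask} on the same grid.
#' @param level dose level in Gy (>= 0).
#' @param mode \code{"pct"} for percent of structure, \code{"cc"} for
#'   absolute volume.
#' @return volume in percent or cc.
#' @export
volume_at_dose <- function(dose, mask, level, mode = c("pct", "cc")) {
  mode <- match.arg(mode)
  if (!sum(mask$voxels)) stop("structure is empty")
  if (!is.numeric(level) || level < 0) stop("level must be >= 0")
  check_same_grid(dose, mask, "dose and structure")
  n_at <- sum(dose$values[mask$voxels] >= level)
  if (mode == "pct") 100 * n_at / sum(mask$voxels)
  else n_at * voxel_volume_mm3(mask$grid) / 1000
}

#' Mean, maximum and minimum structure dose
#'
#' Arithmetic mean / extreme of the dose over structure voxels.
#'
#' @param dose a \code{\link{dose_grid}}.
#' @param mask nonempty \code{binary_mask} on the same grid.
#' @return dose in Gy.
#' @export
mean_dose <- function(dose, mask) {
  if (!sum(mask$voxels)) stop("structure is empty")
  check_same_grid(dose, mask, "dose and structure")
  mean(dose$values[mask$voxels])
}

#' @rdname mean_dose
#' @export
max_dose <- function(dose, mask) {
  if (!sum(mask$voxels)) stop("structure is empty")
  check_same_grid(dose, mask, "dose and structure")
  max(dose$values[mask$voxels])
}

#' @rdname mean_dose
#' @export
min_dose <- function(dose, mask) {
  if (!sum(mask$voxels)) stop("structure is empty")
  check_same_grid(dose, mask, "dose and structure")
  min(dose$values[mask$voxels])
}

# Dose to the hottest `cc` cubic centimetres computed from voxel values
# (used for point metrics such as D0.03cc so the 0.5 cGy binning does not
# quantize maxima). Structures smaller than `cc` fall back to Dmax with a
# message.
dose_to_hottest_cc <- function(dose, mask, cc) {
  if (!sum(mask$voxels)) stop("structure is empty")
  check_same_grid(dose, mask, "dose and structure")
  vv <- voxel_volume_mm3(mask$grid) / 1000
  d <- sort(dose$values[mask$voxels], decreasing = TRUE)
  if (cc > length(d) * vv) {
    message(sprintf(
      "structure smaller than %.3g cc: dose-to-volume falls back to Dmax", cc))
    return(d[1])
  }
  r <- cc / vv                       # fractional voxel rank covering cc
  if (r <= 1) return(d[1])
  lo <- floor(r); hi <- ceiling(r)
  if (lo == hi) return(d[lo])
  d[lo] + (r - lo) * (d[hi] - d[lo])
}

#' Export a DVH as CSV
#'
#' Columns: \code{dose_Gy}, \code{volume_pct}, \code{volume_cc}.
#'
#' @param dvh a \code{\link{cumulative_dvh}} result.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_dvh_csv <- function(dvh, path) {
  df <- data.frame(dose_Gy = dvh$bin_edges,
                   volume_pct = dvh$cum_volume_pct,
                   volume_cc = dvh$cum_volume_pct / 100 * dvh$total_volume_cc)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
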