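#' Gamma-index acceptance criteria
#'
#' Criteria for the 3-D gamma comparison of an evaluated dose distribution
#' against a reference (planned) one: dose-difference tolerance in percent
#' of the normalization dose, distance-to-agreement in mm, global
#' normalization value (typically the prescription dose; a local
#' per-voxel normalization is available behind \code{local}), a low-dose
#' threshold below which reference voxels are excluded, the spatial search
#' bound as a multiple of the DTA, and the subsampling factor refining the
#' evaluated grid by trilinear interpolation.
#'
#' @param dose_diff_pct dose-difference criterion in percent (> 0).
#' @param dta_mm distance-to-agreement in mm (> 0).
#' @param normalization global normalization dose in Gy (> 0).
#' @param low_dose_threshold_pct percent of the normalization below which
#'   reference voxels are excluded (default 10).
#' @param search_radius_factor search radius as a multiple of
#'   \code{dta_mm} (default 3).
#' @param subsample_factor interpolation refinement of the evaluated grid
#'   (default 3).
#' @param local if TRUE, the dose-difference tolerance is taken relative
#'   to the local reference dose instead of the global normalization.
#' @return object of class \code{gamma_criteria}.
#' @export
gamma_criteria <- function(dose_diff_pct, dta_mm, normalization,
                           low_dose_threshold_pct = 10,
                           search_radius_factor = 3,
                           subsample_factor = 3,
                           local = FALSE) {
  if (dose_diff_pct <= 0) stop("dose_diff_pct must be > 0")
  if (dta_mm <= 0) stop("dta_mm must be > 0")
  if (normalization <= 0) stop("normalization must be > 0")
  if (low_dose_threshold_pct < 0) stop("low_dose_threshold_pct must be >= 0")
  structure(list(dose_diff_pct = dose_diff_pct, dta_mm = dta_mm,
                 normalization = normalization,
                 low_dose_threshold_pct = low_dose_threshold_pct,
                 search_radius_factor = search_radius_factor,
                 subsample_factor = as.integer(subsample_factor),
                 local = local),
            class = "gamma_criteria")
}

#' 3-D gamma-index map between two dose grids
#'
#' For each reference voxel at or above the low-dose threshold, gamma is
#' the minimum over evaluated positions within the search radius of
#' sqrt((dose difference / tolerance)^2 + (distance / DTA)^2), with the
#' evaluated dose interpolated trilinearly on a subsampled offset lattice.
#' The comparison is asymmetric: the reference should be the planned
#' (TPS-analogue) distribution.
#'
#' @param reference,evaluated \code{\link{dose_grid}}s on the same grid.
#' @param criteria a \code{\link{gamma_criteria}} object.
#' @return object of class \code{gamma_result}: \code{gamma_field}
#'   (scalar volume values, NA where excluded), \code{pass_rate_pct},
#'   \code{n_included}, \code{criteria}.
#' @export
gamma_map <- function(reference, evaluated, criteria) {
  check_same_grid(reference, evaluated, "reference and evaluated dose")
  g <- .gamma_search_cpp(
    as.numeric(reference$values), as.numeric(evaluated$values),
    as.integer(reference$grid$shape), as.numeric(reference$grid$spacing),
    criteria$dose_diff_pct / 100, criteria$dta_mm,
    criteria$normalization, isTRUE(criteria$local),
    criteria$low_dose_threshold_pct / 100 * criteria$normalization,
    criteria$search_radius_factor * criteria$dta_mm,
    criteria$subsample_factor)
  gf <- array(g, dim = reference$grid$shape)
  included <- !is.na(gf)
  if (!any(included)) stop("no reference voxels above the low-dose threshold")
  res <- structure(list(gamma_field = gf, grid = reference$grid,
                        criteria = criteria,
                        n_included = sum(included)),
                   class = "gamma_result")
  res$pass_rate_pct <- pass_rate(res)
  res
}

#' Gamma pass rate
#'
#' Percent of included voxels (optionally restricted to a region) with
#' gamma at most 1.
#'
#' @param result a \code{\link{gamma_map}} result.
#' @param region optional \code{binary_mask} restricting the tally.
#' @return pass rate in percent.
#' @export
pass_rate <- function(result, region = NULL) {
  g <- result$gamma_field
  keep <- !is.na(g)
  if (!is.null(region)) {
    if (!identical(dim(region$voxels), dim(g)))
      stop("region grid does not match the gamma field")
    keep <- keep & region$voxels
  }
  if (!any(keep)) stop("region contains no included voxels")
  100 * sum(g[keep] <= 1 + 1e-12) / sum(keep)
}

#' @export
print.gamma_result <- function(x, ...) {
  cr <- x$criteria
  cat(sprintf(
    "<gamma_result> %g%%/%g mm (norm %.3g Gy): pass rate %.2f%% over %d voxels\n",
    cr$dose_diff_pct, cr$dta_mm, cr$normalization, x$pass_rate_pct,
    x$n_included))
  invisible(x)
}

#' Gamma report as a list for JSON export
#'
#' Criteria, pass rate and gamma-distribution percentiles of one
#' comparison.
#'
#' @param result a \code{\link{gamma_map}} result.
#' @return named list.
#' @export
gamma_report <- function(result) {
  g <- result$gamma_field[!is.na(result$gamma_field)]
  qs <- quantile(g, c(0.5, 0.9, 0.95, 0.99), type = 7, names = FALSE)
  list(dose_diff_pct = result$criteria$dose_diff_pct,
       dta_mm = result$criteria$dta_mm,
       normalization_Gy = result$criteria$normalization,
       low_dose_threshold_pct = result$criteria$low_dose_threshold_pct,
       n_included = result$n_included,
       pass_rate_pct = result$pass_rate_pct,
       gamma_p50 = qs[1], gamma_p90 = qs[2], gamma_p95 = qs[3],
       gamma_p99 = qs[4], gamma_max = max(g))
}
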