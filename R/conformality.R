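#' Isodose volumes for conformality metrics
#'
#' Shared inputs of the SBRT conformality indices: the prescription
#' isodose volume (PIV, body tissue at or above the prescription dose px),
#' the part of the target inside it (TV_PIV), and the half-prescription
#' isodose volume (V50).
#'
#' @param dose \code{\link{dose_grid}}.
#' @param px prescription dose in Gy (> 0).
#' @param tv target \code{binary_mask} (the BTV for the boost phase).
#' @param body body \code{binary_mask}; must contain \code{tv}.
#' @return list with \code{piv_cc}, \code{tv_piv_cc}, \code{v50_cc}.
#' @export
isodose_volumes <- function(dose, px, tv, body) {
  if (!is.numeric(px) || px <= 0) stop("px must be > 0")
  if (!sum(body$voxels)) stop("body mask is empty")
  check_same_grid(dose, body, "dose and body")
  check_same_grid(dose, tv, "dose and target")
  if (!mask_subset(tv, body)) stop("target must lie inside the body")
  vv <- voxel_volume_mm3(dose$grid) / 1000
  at_px <- dose$values >= px
  list(piv_cc = sum(at_px & body$voxels) * vv,
       tv_piv_cc = sum(at_px & tv$voxels) * vv,
       v50_cc = sum(dose$values >= 0.5 * px & body$voxels) * vv)
}

#' SBRT conformality and spillage report for a boost plan
#'
#' Computes the conformality block of a single-fraction boost evaluation:
#' \itemize{
#'   \item PDS (prescription dose spillage) = PIV / TV (default convention,
#'     see \code{pds_denominator});
#'   \item MGI (modified gradient index) = V50 / PIV;
#'   \item R50 = V50 / TV;
#'   \item RTOG CI = PIV / TV (alternative coverage convention
#'     TV_PIV / TV also reported as \code{rtog_ci_coverage});
#'   \item Paddick CI = TV_PIV^2 / (TV x PIV);
#'   \item NTT = PIV - TV_PIV in cc (non-target tissue at prescription
#'     dose);
#'   \item NTT_2cm = maximum dose at least 20 mm from the PTV, in percent
#'     of px;
#'   \item bladder Dmean in percent of px.
#' }
#' When the PIV is empty, MGI and the Paddick CI are undefined and
#' returned as NA with \code{flags$piv_empty} set.
#'
#' @param dose \code{\link{dose_grid}}.
#' @param px prescription dose in Gy.
#' @param tv target volume mask (BTV).
#' @param body body mask.
#' @param ptv planning target mask used for the 2 cm shell (defaults to
#'   \code{tv}: the boost PTV equals the BTV here).
#' @param bladder optional bladder mask.
#' @param pds_denominator \code{"tv"} (default) or \code{"piv_coverage"}
#'   switching the PDS convention.
#' @return object of class \code{conformality_report}.
#' @export
conformality_report <- function(dose, px, tv, body, ptv = tv,
                                bladder = NULL,
                                pds_denominator = c("tv", "piv_coverage")) {
  pds_denominator <- match.arg(pds_denominator)
  iso <- isodose_volumes(dose, px, tv, body)
  tv_cc <- volume_cc(tv)
  flags <- list(piv_empty = iso$piv_cc == 0, shell_empty = FALSE)
  pds <- if (pds_denominator == "tv") iso$piv_cc / tv_cc
         else iso$tv_piv_cc / iso$piv_cc
  rtog_ci <- iso$piv_cc / tv_cc
  rtog_ci_coverage <- iso$tv_piv_cc / tv_cc
  if (flags$piv_empty) {
    mgi <- NA_real_
    paddick <- NA_real_
  } else {
    mgi <- iso$v50_cc / iso$piv_cc
    paddick <- iso$tv_piv_cc^2 / (tv_cc * iso$piv_cc)
  }
  r50 <- iso$v50_cc / tv_cc
  ntt_px_cc <- iso$piv_cc - iso$tv_piv_cc
  shell <- shell_beyond(ptv, 20, body)
  if (sum(shell$voxels)) {
    ntt_2cm_pct <- 100 * max_dose(dose, shell) / px
  } else {
    ntt_2cm_pct <- NA_real_
    flags$shell_empty <- TRUE
  }
  bladder_dmean_pct <- if (is.null(bladder)) NA_real_
                       else 100 * mean_dose(dose, bladder) / px
  structure(list(
    px = px, pds = pds, mgi = mgi, r50 = r50, rtog_ci = rtog_ci,
    rtog_ci_coverage = rtog_ci_coverage, paddick_ci = paddick,
    ntt_px_cc = ntt_px_cc, ntt_2cm_pct = ntt_2cm_pct,
    bladder_dmean_pct = bladder_dmean_pct,
    piv_cc = iso$piv_cc, tv_cc = tv_cc, tv_piv_cc = iso$tv_piv_cc,
    v50_cc = iso$v50_cc, ptv_cc = volume_cc(ptv), flags = flags),
    class = "conformality_report")
}

#' @export
print.conformality_report <- function(x, ...) {
  cat(sprintf(paste0("<conformality_report> px %.3g Gy: PDS %.3f, MGI %.3f,",
                     " R50 %.3f, RTOG CI %.3f, Paddick CI %.3f, NTT %.2f cc,",
                     " NTT_2cm %.1f%%\n"),
              x$px, x$pds, x$mgi, x$r50, x$rtog_ci, x$paddick_ci,
              x$ntt_px_cc, x$ntt_2cm_pct))
  invisible(x)
}

#' Reference limit table keyed by PTV volume
#'
#' Protocol reference limits (R50, maximum dose at 2 cm) tabulated against
#' PTV volume. Rows must be strictly increasing in \code{ptv_cc}.
#'
#' @param ptv_cc numeric vector of PTV volumes in cc (strictly increasing,
#'   length >= 2).
#' @param limit numeric vector of limit values, same length.
#' @param metric label for the limited metric.
#' @return object of class \code{reference_limit_table}.
#' @export
reference_limit_table <- function(ptv_cc, limit, metric = "limit") {
  if (length(ptv_cc) < 2L) stop("a reference table needs at least 2 rows")
  if (length(limit) != length(ptv_cc)) stop("ptv_cc and limit lengths differ")
  if (any(diff(ptv_cc) <= 0)) stop("ptv_cc must be strictly increasing")
  structure(list(ptv_cc = as.numeric(ptv_cc), limit = as.numeric(limit),
                 metric = metric),
            class = "reference_limit_table")
}

#' Interpolate a PTV-volume-dependent reference limit
#'
#' Piecewise-linear interpolation between bracketing table rows; outside
#' the tabulated range the first/last segment is extended linearly
#' (extrapolation).
#'
#' @param table a \code{\link{reference_limit_table}}.
#' @param ptv_cc PTV volume in cc.
#' @return the interpolated limit value.
#' @export
interpolate_limit <- function(table, ptv_cc) {
  x <- table$ptv_cc; y <- table$limit
  n <- length(x)
  if (ptv_cc <= x[1])
    return(y[1] + (ptv_cc - x[1]) * (y[2] - y[1]) / (x[2] - x[1]))
  if (ptv_cc >= x[n])
    return(y[n] + (ptv_cc - x[n]) * (y[n] - y[n - 1]) / (x[n] - x[n - 1]))
  stats::approx(x, y, xout = ptv_cc)$y
}

#' Load reference limit tables from a YAML config
#'
#' Reads PTV-volume-keyed reference rows (as shipped in
#' \code{inst/extdata/rtog0813_reference.yaml}) into
#' \code{\link{reference_limit_table}} objects. Each metric carries a
#' \code{none} (primary) and \code{minor} (acceptable variation) column.
#'
#' @param path YAML file; default: the packaged protocol reference values.
#' @return named list of lists with \code{none}/\code{minor} tables.
#' @export
load_reference_limits <- function(path = system.file(
  "extdata", "rtog0813_reference.yaml", package = "adcboost")) {
  cfg <- yaml::read_yaml(path)
  out <- lapply(names(cfg), function(metric) {
    m <- cfg[[metric]]
    rows <- do.call(rbind, lapply(m$rows, unlist))
    list(none = reference_limit_table(rows[, "ptv_cc"], rows[, "none"],
                                      metric = metric),
         minor = reference_limit_table(rows[, "ptv_cc"], rows[, "minor"],
                                       metric = metric))
  })
  names(out) <- names(cfg)
  out
}
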