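#' Segment the restricted-diffusion subvolume (C40)
#'
#' Thresholds the ADC map at the given intra-tumoural percentile: the
#' threshold is the \code{centile}-th percentile of ADC values over GTV
#' voxels (linear interpolation between order statistics), and the
#' returned mask holds the GTV voxels with ADC at or below it. Low ADC
#' indicates restricted diffusion, associated with dense tumour; the
#' default 40th centile yields the C40 boost nucleus.
#'
#' @param adc an \code{\link{adc_map}} on the same grid as \code{gtv}.
#' @param gtv nonempty \code{binary_mask} of the gross tumour volume.
#' @param centile percentile in (0, 100); default 40.
#' @return list with \code{mask} (\code{binary_mask}) and \code{threshold}
#'   (ADC units).
#' @export
c40_segment <- function(adc, gtv, centile = 40) {
  if (!sum(gtv$voxels)) stop("GTV is empty")
  if (!is.numeric(centile) || centile <= 0 || centile >= 100)
    stop("centile must lie strictly between 0 and 100")
  check_same_grid(adc, gtv, "ADC map and GTV")
  vals <- adc$values[gtv$voxels]
  threshold <- as.numeric(quantile(vals, centile / 100, type = 7,
                                   names = FALSE))
  mask <- binary_mask(gtv$voxels & adc$values <= threshold, gtv$grid,
                      name = "C40")
  list(mask = mask, threshold = threshold)
}

#' Build the boost target volume (BTV)
#'
#' Expands the cleaned C40 subvolume by anisotropic margins (default
#' 11 mm anteroposteriorly, 7 mm transverse, 13 mm craniocaudally) and
#' clips the result to the CTV.
#'
#' @param c40 \code{binary_mask}, must be contained in \code{ctv}.
#' @param ctv nonempty \code{binary_mask} of the clinical target volume.
#' @param m expansion \code{\link{margins}}.
#' @return \code{binary_mask} of the BTV (C40 subset of BTV subset of CTV).
#' @export
build_btv <- function(c40, ctv,
                      m = margins(anteroposterior = 11, transverse = 7,
                                  craniocaudal = 13)) {
  if (!sum(c40$voxels)) stop("C40 is empty")
  if (!sum(ctv$voxels)) stop("CTV is empty")
  if (!mask_subset(c40, ctv))
    stop("C40 extends outside the CTV: inconsistent upstream contours")
  btv <- expand_mask(c40, m, limit = ctv)
  btv$name <- "BTV"
  btv
}

#' Build the dose-fall-off evaluation structure (EVAL)
#'
#' EVAL is the BTV minus the C40 expanded isotropically by 1 mm. Dose
#' within EVAL must stay below 110% of the boost prescription, verifying a
#' steep fall-off from the boosted nucleus. The result may be empty.
#'
#' @param btv \code{binary_mask}; must contain \code{c40}.
#' @param c40 \code{binary_mask}.
#' @param buffer_mm isotropic buffer around C40 in mm (default 1).
#' @return \code{binary_mask} of the EVAL shell.
#' @export
build_eval <- function(btv, c40, buffer_mm = 1) {
  check_same_grid(btv, c40, "BTV and C40")
  if (!mask_subset(c40, btv)) stop("C40 must be contained in the BTV")
  ring <- expand_mask(c40, margins(buffer_mm, buffer_mm, buffer_mm))
  out <- subtract_mask(btv, ring)
  out$name <- "EVAL"
  out
}

#' Delineate all boost structures from an ADC map and GTV/CTV contours
#'
#' Full semi-automatic chain: percentile segmentation of the
#' restricted-diffusion subvolume, cleaning of non-contiguous voxels
#' (largest 26-connected component), margin growth into the BTV clipped to
#' the CTV, and construction of the EVAL fall-off shell.
#'
#' @param adc \code{\link{adc_map}}.
#' @param gtv,ctv \code{binary_mask}s on the same grid (GTV inside CTV).
#' @param centile ADC percentile for the subvolume (default 40).
#' @param m BTV expansion \code{\link{margins}}.
#' @return list of class \code{boost_structures}: \code{c40}, \code{btv},
#'   \code{eval_structure}, \code{adc_threshold}, \code{n_components}.
#' @export
delineate_boost <- function(adc, gtv, ctv, centile = 40,
                            m = margins(anteroposterior = 11, transverse = 7,
                                        craniocaudal = 13)) {
  if (!mask_subset(gtv, ctv)) stop("GTV extends outside the CTV")
  seg <- c40_segment(adc, gtv, centile)
  c40 <- clean_noncontiguous(seg$mask)
  btv <- build_btv(c40, ctv, m)
  ev <- build_eval(btv, c40)
  structure(list(c40 = c40, btv = btv, eval_structure = ev,
                 adc_threshold = seg$threshold,
                 n_components = attr(c40, "n_components")),
            class = "boost_structures")
}

#' @export
print.boost_structures <- function(x, ...) {
  cat(sprintf(paste0("<boost_structures> C40 %.1f cc (ADC threshold %.4g,",
                     " %d component(s)), BTV %.1f cc, EVAL %.1f cc\n"),
              volume_cc(x$c40), x$adc_threshold, x$n_components,
              volume_cc(x$btv), volume_cc(x$eval_structure)))
  invisible(x)
}

#' Write delineation outputs to a directory
#'
#' Writes C40/BTV/EVAL masks as NIfTI plus a JSON sidecar with the ADC
#' threshold, component count and volumes in cc.
#'
#' @param bs a \code{boost_structures} object.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_boost_structures <- function(bs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_nifti(bs$c40, file.path(dir, "c40.nii.gz"))
  write_nifti(bs$btv, file.path(dir, "btv.nii.gz"))
  write_nifti(bs$eval_structure, file.path(dir, "eval.nii.gz"))
  sidecar <- list(
    adc_threshold = bs$adc_threshold,
    n_components = bs$n_components,
    volumes_cc = list(c40 = volume_cc(bs$c40), btv = volume_cc(bs$btv),
                      eval = volume_cc(bs$eval_structure)))
  jsonlite::write_json(sidecar, file.path(dir, "delineation.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
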