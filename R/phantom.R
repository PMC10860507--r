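# Synthetic pelvis phantom: seeded generator of pelvis-like geometry with
# a low-ADC intra-tumoural focus, nested target structures, organs at
# risk, and analytic dose fields with plateau-plus-exponential falloff.
# Geometry is fully determined by the spec; only the ADC noise (and
# cohort jitter) consume random numbers.

# ellipsoid membership on a grid, all lengths in mm, axes (cc, ap, tr)
ellipsoid_mask <- function(grid, center, semi, name = NULL) {
  co <- coord_arrays(grid)
  inside <- ((co$cc - center[1]) / semi[1])^2 +
            ((co$ap - center[2]) / semi[2])^2 +
            ((co$tr - center[3]) / semi[3])^2 <= 1
  binary_mask(inside, grid, name = name)
}

# straight tube along the craniocaudal axis at (ap0, tr0), clipped to body
tube_mask_cc <- function(grid, ap0, tr0, radius, cc_range, body,
                         name = NULL) {
  i_ap <- which.min(abs(axis_coords(grid, 2) - ap0))
  i_tr <- which.min(abs(axis_coords(grid, 3) - tr0))
  cc <- axis_coords(grid, 1)
  path <- array(FALSE, dim = grid$shape)
  path[cc >= cc_range[1] & cc <= cc_range[2], i_ap, i_tr] <- TRUE
  tube <- expand_mask(binary_mask(path, grid),
                      margins(radius, radius, radius), limit = body)
  tube$name <- name
  tube
}

# same, running along the transverse axis at (cc0, ap0)
tube_mask_tr <- function(grid, cc0, ap0, radius, tr_range, body,
                         name = NULL) {
  i_cc <- which.min(abs(axis_coords(grid, 1) - cc0))
  i_ap <- which.min(abs(axis_coords(grid, 2) - ap0))
  tr <- axis_coords(grid, 3)
  path <- array(FALSE, dim = grid$shape)
  path[i_cc, i_ap, tr >= tr_range[1] & tr <= tr_range[2]] <- TRUE
  tube <- expand_mask(binary_mask(path, grid),
                      margins(radius, radius, radius), limit = body)
  tube$name <- name
  tube
}

#' Specification of the synthetic pelvis phantom
#'
#' Describes a pelvis-like geometry on a regular grid (default 96^3 voxels
#' at 2 mm): a body ellipsoid, a gross tumour volume in the posterior
#' pelvis sized to a realistic rectal tumour (about 53 cc, 5 cm
#' craniocaudal length), an ADC model with a low-diffusion focus planted
#' inside the GTV, clinical and planning target margins, and organs at
#' risk (anterior bladder sphere, large- and small-bowel tubes, and a
#' bowel-cavity envelope). All positions are voxel-center mm coordinates
#' on the internal (craniocaudal, anteroposterior, transverse) axes.
#'
#' The \code{"compliant"} preset keeps the bladder and bowel clear of the
#' high-dose region; the \code{"stressed"} preset pushes the bladder into
#' the planning target and routes the large bowel through the
#' intermediate-dose region, reproducing the constraint families that
#' limit dose escalation in practice (bladder V45/Dmax, large-bowel V45).
#'
#' @param preset \code{"compliant"} (default) or \code{"stressed"}.
#' @param shape,spacing grid definition.
#' @param gtv_center,gtv_semi GTV ellipsoid center and semi-axes in mm.
#' @param adc_background mean background ADC inside the body (arbitrary
#'   units; percentile segmentation is scale-invariant).
#' @param adc_noise_sd Gaussian ADC noise standard deviation.
#' @param focus_center,focus_radius low-ADC focus ball (defaults to the
#'   GTV center).
#' @param depression_frac fractional ADC depression inside the focus
#'   (default 0.30).
#' @param ctv_margins \code{\link{margins}} growing GTV to CTV.
#' @param ptv_margin_mm isotropic CTV-to-PTV margin.
#' @param bladder_center,bladder_radius bladder sphere (preset-dependent
#'   default position).
#' @param large_bowel,small_bowel lists with tube position fields
#'   (preset-dependent defaults).
#' @return object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(preset = c("compliant", "stressed"),
                         shape = c(96, 96, 96), spacing = c(2, 2, 2),
                         gtv_center = c(95, 120, 95),
                         gtv_semi = c(25, 18, 28),
                         adc_background = 1200, adc_noise_sd = 60,
                         focus_center = gtv_center, focus_radius = 18,
                         depression_frac = 0.30,
                         ctv_margins = margins(anteroposterior = 12,
                                               transverse = 12,
                                               craniocaudal = 15),
                         ptv_margin_mm = 7,
                         bladder_center = NULL, bladder_radius = 28,
                         large_bowel = NULL,
                         small_bowel = list(cc = 168, ap = 60, radius = 12,
                                            tr_range = c(45, 145))) {
  preset <- match.arg(preset)
  if (is.null(bladder_center))
    bladder_center <- if (preset == "compliant") c(95, 45, 95)
                      else c(95, 75, 95)
  if (is.null(large_bowel))
    large_bowel <- if (preset == "compliant")
      list(ap = 60, tr = 150, radius = 12, cc_range = c(20, 170))
    else
      list(ap = 100, tr = 135, radius = 15, cc_range = c(20, 170))
  structure(list(
    preset = preset, shape = shape, spacing = spacing,
    body_center = c(95, 95, 95), body_semi = c(88, 85, 88),
    gtv_center = gtv_center, gtv_semi = gtv_semi,
    adc_background = adc_background, adc_noise_sd = adc_noise_sd,
    focus_center = focus_center, focus_radius = focus_radius,
    depression_frac = depression_frac,
    ctv_margins = ctv_margins, ptv_margin_mm = ptv_margin_mm,
    bladder_center = bladder_center, bladder_radius = bladder_radius,
    large_bowel = large_bowel, small_bowel = small_bowel),
    class = "phantom_spec")
}

# error if a structure reaches the grid boundary
check_in_grid <- function(mask, what) {
  v <- mask$voxels
  d <- dim(v)
  touches <- any(v[1, , ]) || any(v[d[1], , ]) ||
             any(v[, 1, ]) || any(v[, d[2], ]) ||
             any(v[, , 1]) || any(v[, , d[3]])
  if (touches) stop(sprintf("structure '%s' extends to the grid boundary",
                            what))
  invisible(TRUE)
}

#' Generate a synthetic pelvis phantom
#'
#' Builds the ADC map and all structure masks from a
#' \code{\link{phantom_spec}}. Geometry is seed-free; the seed only drives
#' the ADC noise, so two seeds share identical masks. The ADC inside the
#' body is Gaussian around the background mean, depressed by
#' \code{depression_frac} of the background inside the planted focus ball,
#' and clipped at zero.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @param seed RNG seed for the ADC noise.
#' @return list of class \code{phantom}: \code{adc} (an
#'   \code{\link{adc_map}}) and \code{structures} (named list of
#'   \code{binary_mask}s: gtv, ctv, ptv, body, bladder, large_bowel,
#'   small_bowel, bowel_cavity).
#' @export
generate_phantom <- function(spec = phantom_spec(), seed = 1) {
  grid <- image_grid(spec$shape, spec$spacing)
  body <- ellipsoid_mask(grid, spec$body_center, spec$body_semi, "body")
  gtv <- ellipsoid_mask(grid, spec$gtv_center, spec$gtv_semi, "GTV")
  if (!mask_subset(gtv, body)) stop("GTV extends outside the body")
  ctv <- expand_mask(gtv, spec$ctv_margins, limit = body)
  ctv$name <- "CTV"
  p <- spec$ptv_margin_mm
  ptv <- expand_mask(ctv, margins(p, p, p), limit = body)
  ptv$name <- "PTV"
  bladder <- ellipsoid_mask(grid, spec$bladder_center,
                            rep(spec$bladder_radius, 3), "bladder")
  lb <- tube_mask_cc(grid, spec$large_bowel$ap, spec$large_bowel$tr,
                     spec$large_bowel$radius, spec$large_bowel$cc_range,
                     body, "large_bowel")
  sb <- tube_mask_tr(grid, spec$small_bowel$cc, spec$small_bowel$ap,
                     spec$small_bowel$radius, spec$small_bowel$tr_range,
                     body, "small_bowel")
  cavity <- expand_mask(union_mask(lb, sb), margins(8, 8, 8), limit = body)
  cavity$name <- "bowel_cavity"
  for (st in list(gtv, ctv, ptv, bladder))
    check_in_grid(st, st$name)

  set.seed(seed)
  co <- coord_arrays(grid)
  adc_vals <- spec$adc_background +
    array(rnorm(prod(grid$shape), 0, spec$adc_noise_sd), dim = grid$shape)
  focus <- (co$cc - spec$focus_center[1])^2 +
           (co$ap - spec$focus_center[2])^2 +
           (co$tr - spec$focus_center[3])^2 <= spec$focus_radius^2
  adc_vals[focus] <- adc_vals[focus] -
    spec$depression_frac * spec$adc_background
  adc_vals[adc_vals < 0] <- 0
  structure(list(
    adc = adc_map(adc_vals, grid),
    structures = list(gtv = gtv, ctv = ctv, ptv = ptv, body = body,
                      bladder = bladder, large_bowel = lb,
                      small_bowel = sb, bowel_cavity = cavity),
    spec = spec, seed = seed),
    class = "phantom")
}

#' Structure centroid in mm
#' @param mask nonempty \code{binary_mask}.
#' @return numeric length 3, centroid of voxel centers (cc, ap, tr) in mm.
#' @export
centroid_mm <- function(mask) {
  if (!sum(mask$voxels)) stop("mask is empty")
  co <- coord_arrays(mask$grid)
  c(mean(co$cc[mask$voxels]), mean(co$ap[mask$voxels]),
    mean(co$tr[mask$voxels]))
}

#' Analytic dose model
#'
#' A plateau-plus-exponential-falloff surrogate for an optimized
#' conformal plan: dose is \code{px * plateau_level} inside the target and
#' halves every \code{falloff_half_distance} mm outside it, measured from
#' the target surface (the boundary of the union of target voxel cubes).
#' An optional Gaussian hotspot models the deliberate dose escalation of
#' the boost nucleus.
#'
#' @param px prescription dose in Gy.
#' @param plateau_level dose inside the target as a fraction of px
#'   (>= 1 for a compliant plan).
#' @param falloff_half_distance dose-halving distance outside the target
#'   in mm (> 0).
#' @param hotspot optional list with \code{center} (mm, cc/ap/tr),
#'   \code{peak} (fraction of px, at most 1.25 for a compliant boost) and
#'   \code{sigma_mm} (Gaussian width).
#' @param phase \code{"boost"} or \code{"conventional"} (label only).
#' @return object of class \code{dose_model}.
#' @export
dose_model <- function(px, plateau_level = 1.01, falloff_half_distance = 5,
                       hotspot = NULL, phase = c("boost", "conventional")) {
  phase <- match.arg(phase)
  if (px <= 0) stop("px must be > 0")
  if (falloff_half_distance <= 0)
    stop("falloff_half_distance must be > 0")
  structure(list(px = px, plateau_level = plateau_level,
                 falloff_half_distance = falloff_half_distance,
                 hotspot = hotspot, phase = phase),
            class = "dose_model")
}

# distance (mm) from each voxel center to the target surface: 0 inside;
# outside, the center-to-nearest-target-center distance minus a
# quarter-voxel. Voxel centers sample the structure, so the implicit
# surface lies beyond the outermost centers; the quarter-voxel offset
# makes dilation volumes of smooth voxelized shapes agree with the
# continuum (raw center distances under-dilate, full half-voxel
# correction over-dilates).
surface_distance <- function(target) {
  grid <- target$grid
  ft <- edt_transform(target$voxels, grid$spacing)
  d <- array(pmax(sqrt(ft$dist2) - mean(grid$spacing) / 4, 0),
             dim = grid$shape)
  d[target$voxels] <- 0
  d
}

#' Analytic dose field for a target
#'
#' Evaluates a \code{\link{dose_model}} on the grid of a target mask:
#' plateau inside the target, exponential (half-distance) falloff outside,
#' plus the optional hotspot. The field is continuous and monotone
#' non-increasing with distance outside the target.
#'
#' @param target nonempty \code{binary_mask}.
#' @param model a \code{\link{dose_model}}.
#' @return \code{\link{dose_grid}} on the target's grid.
#' @export
analytic_dose <- function(target, model) {
  if (!sum(target$voxels)) stop("target is empty")
  d <- surface_distance(target)
  dose <- model$px * model$plateau_level *
    2^(-d / model$falloff_half_distance)
  hs <- model$hotspot
  if (!is.null(hs)) {
    co <- coord_arrays(target$grid)
    r2 <- (co$cc - hs$center[1])^2 + (co$ap - hs$center[2])^2 +
          (co$tr - hs$center[3])^2
    dose <- dose + model$px * (hs$peak - model$plateau_level) *
      exp(-r2 / (2 * hs$sigma_mm^2))
  }
  dose_grid(dose, target$grid)
}

#' Rigidly perturb a dose grid
#'
#' Shifted (trilinear resampling), scaled, noise-added copy of a dose
#' field, used as the evaluated distribution in gamma-comparison tests.
#' Voxels sampled from outside the original grid are set to zero.
#'
#' @param dose a \code{\link{dose_grid}}.
#' @param shift_mm rigid shift in mm along (cc, ap, tr).
#' @param scale multiplicative dose scaling.
#' @param noise_sd additive Gaussian noise standard deviation in Gy.
#' @param seed optional RNG seed for the noise.
#' @return perturbed \code{dose_grid}.
#' @export
perturb_dose <- function(dose, shift_mm = c(0, 0, 0), scale = 1,
                         noise_sd = 0, seed = NULL) {
  extent <- (dose$grid$shape - 1) * dose$grid$spacing
  if (any(abs(shift_mm) >= extent))
    stop("shift exceeds the grid extent")
  vals <- .resample_shift_cpp(as.numeric(dose$values),
                              as.integer(dose$grid$shape),
                              as.numeric(dose$grid$spacing),
                              as.numeric(shift_mm))
  vals <- array(vals, dim = dose$grid$shape) * scale
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    vals <- vals + array(rnorm(length(vals), 0, noise_sd),
                         dim = dose$grid$shape)
  }
  vals[vals < 0] <- 0
  dose_grid(vals, dose$grid)
}

#' Generate a phantom cohort with boost, conventional and summed plans
#'
#' Produces \code{n} subjects with seeded per-subject geometry jitter
#' (GTV size scaling and focus offset), delineates the boost structures
#' from each subject's ADC map, and attaches analytic dose fields: one
#' boost plan per prescription level (plateau covering the BTV with a
#' hotspot at the cleaned subvolume centroid), a two-level conventional
#' long-course plan (elective 45 Gy volume with a simultaneous 50 Gy
#' boost volume), and the physical sums.
#'
#' @param n number of subjects (>= 1).
#' @param base_spec a \code{\link{phantom_spec}} to jitter.
#' @param seed top-level RNG seed; all per-subject randomness derives
#'   from it.
#' @param boost_px boost prescription levels in Gy (default 5, 7, 10).
#' @param conventional_px long-course prescription in Gy (default 50).
#' @param boost_model_args overrides for the boost
#'   \code{\link{dose_model}} (plateau_level, falloff_half_distance,
#'   hotspot peak/sigma).
#' @return list of class \code{phantom_cohort}; each subject holds
#'   \code{phantom}, \code{boost} (a \code{boost_structures}),
#'   \code{ptv4500}, and \code{doses} (per-level boost, conventional,
#'   per-level summed).
#' @export
generate_cohort <- function(n, base_spec = phantom_spec(), seed = 1,
                            boost_px = c(5, 7, 10), conventional_px = 50,
                            boost_model_args = list()) {
  if (n < 1) stop("n must be >= 1")
  set.seed(seed)
  scales <- runif(n, 0.9, 1.1)
  jitters <- matrix(runif(3 * n, -3, 3), nrow = n)
  sub_seeds <- sample.int(.Machine$integer.max - 1, n)
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    spec_i <- base_spec
    spec_i$gtv_semi <- base_spec$gtv_semi * scales[i]
    spec_i$focus_radius <- base_spec$focus_radius * scales[i]
    spec_i$focus_center <- base_spec$focus_center + jitters[i, ]
    ph <- generate_phantom(spec_i, seed = sub_seeds[i])
    bs <- delineate_boost(ph$adc, ph$structures$gtv, ph$structures$ctv)
    hs_center <- centroid_mm(bs$c40)
    boost_doses <- lapply(boost_px, function(px) {
      args <- utils::modifyList(
        list(px = px, plateau_level = 1.01, falloff_half_distance = 5,
             hotspot = list(center = hs_center, peak = 1.12, sigma_mm = 5),
             phase = "boost"),
        boost_model_args)
      analytic_dose(bs$btv, do.call(dose_model, args))
    })
    names(boost_doses) <- paste0(boost_px, "Gy")
    # two-level conventional phase: elective volume plus integrated boost
    ptv4500 <- expand_mask(ph$structures$ptv, margins(10, 10, 10),
                           limit = ph$structures$body)
    ptv4500$name <- "PTV4500"
    d45 <- analytic_dose(ptv4500,
                         dose_model(px = conventional_px * 0.9,
                                    plateau_level = 1.02,
                                    falloff_half_distance = 12,
                                    phase = "conventional"))
    d50 <- analytic_dose(ph$structures$ptv,
                         dose_model(px = conventional_px,
                                    plateau_level = 1.02,
                                    falloff_half_distance = 12,
                                    phase = "conventional"))
    conventional <- dose_grid(pmax(d45$values, d50$values), ph$adc$grid)
    summed <- lapply(boost_doses, function(b) sum_dose(b, conventional))
    subjects[[i]] <- list(phantom = ph, boost = bs, ptv4500 = ptv4500,
                          doses = list(boost = boost_doses,
                                       conventional = conventional,
                                       summed = summed))
  }
  structure(list(subjects = subjects, boost_px = boost_px,
                 conventional_px = conventional_px, seed = seed,
                 preset = base_spec$preset),
            class = "phantom_cohort")
}
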