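# Conformality indices, isodose volumes, reference-limit interpolation.

# radial dose profile on a 1 mm grid: >= px inside r_px, half px at r_50
radial_plan <- function(n = 56, px = 5, r_tv = 15, r_px = 16, r_50 = 24) {
  g <- image_grid(c(n, n, n), c(1, 1, 1))
  co <- adcboost:::coord_arrays(g)
  ctr <- rep((n - 1) / 2 + 0.25, 3)
  r <- sqrt((co$cc - ctr[1])^2 + (co$ap - ctr[2])^2 + (co$tr - ctr[3])^2)
  halving <- (r_50 - r_px) / 1            # dose halves from r_px to r_50
  dose <- px * 2^(-(pmax(r, r_px) - r_px) / (r_50 - r_px))
  list(dose = dose_grid(array(dose, dim = c(n, n, n)), g),
       tv = binary_mask(r <= r_tv, g),
       body = binary_mask(array(TRUE, c(n, n, n)), g),
       px = px, r_tv = r_tv, r_px = r_px, r_50 = r_50)
}

test_that("isodose volumes for trivial fields", {
  g <- image_grid(c(12, 12, 12), c(1, 1, 1))
  v <- array(FALSE, c(12, 12, 12)); v[4:8, 4:8, 4:8] <- TRUE
  tv <- binary_mask(v, g)
  body <- binary_mask(array(TRUE, c(12, 12, 12)), g)
  dv <- array(0, c(12, 12, 12)); dv[v] <- 5
  iso <- isodose_volumes(dose_grid(dv, g), 5, tv, body)
  expect_equal(iso$piv_cc, volume_cc(tv))
  expect_equal(iso$tv_piv_cc, volume_cc(tv))
  expect_equal(iso$v50_cc, volume_cc(tv))
  iso0 <- isodose_volumes(dose_grid(array(0, c(12, 12, 12)), g), 5, tv, body)
  expect_equal(unlist(iso0), c(piv_cc = 0, tv_piv_cc = 0, v50_cc = 0))
  expect_error(isodose_volumes(dose_grid(dv, g), 0, tv, body))
})

test_that("perfect conformality yields unit indices and zero spillage", {
  g <- image_grid(c(16, 16, 16), c(2, 2, 2))
  v <- array(FALSE, c(16, 16, 16)); v[6:11, 6:11, 6:11] <- TRUE
  tv <- binary_mask(v, g)
  body <- binary_mask(array(TRUE, c(16, 16, 16)), g)
  dv <- array(0, c(16, 16, 16)); dv[v] <- 5
  rep <- conformality_report(dose_grid(dv, g), 5, tv, body)
  expect_equal(rep$pds, 1)
  expect_equal(rep$rtog_ci, 1)
  expect_equal(rep$paddick_ci, 1)
  expect_equal(rep$ntt_px_cc, 0)
})

test_that("concentric-sphere plan reproduces radii-cubed closed forms", {
  p <- radial_plan()
  rep <- conformality_report(p$dose, p$px, p$tv, p$body)
  vol <- function(R) 4 / 3 * pi * R^3
  expect_equal(rep$pds, vol(p$r_px) / vol(p$r_tv), tolerance = 0.02)
  expect_equal(rep$rtog_ci, vol(p$r_px) / vol(p$r_tv), tolerance = 0.02)
  expect_equal(rep$mgi, vol(p$r_50) / vol(p$r_px), tolerance = 0.02)
  expect_equal(rep$r50, vol(p$r_50) / vol(p$r_tv), tolerance = 0.02)
  expect_equal(rep$paddick_ci, vol(p$r_tv) / vol(p$r_px), tolerance = 0.02)
})

test_that("index identities hold exactly on arbitrary plans", {
  set.seed(40)
  for (case in 1:5) {
    g <- image_grid(c(14, 14, 14), c(1.5, 2, 1.5))
    v <- array(FALSE, c(14, 14, 14)); v[4:10, 4:10, 4:10] <- TRUE
    tv <- binary_mask(v, g)
    body <- binary_mask(array(TRUE, c(14, 14, 14)), g)
    d <- dose_grid(array(runif(14^3, 0, 7), dim = c(14, 14, 14)), g)
    rep <- conformality_report(d, 5, tv, body)
    # MGI and R50 share V50: mgi * piv = r50 * tv
    expect_equal(rep$mgi * rep$piv_cc, rep$r50 * rep$tv_cc,
                 tolerance = 1e-12)
    # Paddick = coverage x selectivity
    expect_equal(rep$paddick_ci,
                 (rep$tv_piv_cc / rep$tv_cc) * (rep$tv_piv_cc / rep$piv_cc),
                 tolerance = 1e-12)
    expect_lte(rep$paddick_ci, 1)
    # volume conservation of non-target tissue
    expect_equal(rep$ntt_px_cc + rep$tv_piv_cc, rep$piv_cc,
                 tolerance = 1e-12)
  }
})

test_that("steeper falloff shrinks the gradient indices", {
  g <- image_grid(c(40, 40, 40), c(2, 2, 2))
  co <- adcboost:::coord_arrays(g)
  r <- sqrt((co$cc - 39)^2 + (co$ap - 39)^2 + (co$tr - 39)^2)
  tv <- binary_mask(r <= 16, g)
  body <- binary_mask(array(TRUE, c(40, 40, 40)), g)
  reps <- lapply(c(4, 8, 12), function(h) {
    d <- analytic_dose(tv, dose_model(5, plateau_level = 1.02,
                                      falloff_half_distance = h))
    conformality_report(d, 5, tv, body)
  })
  expect_lt(reps[[1]]$mgi, reps[[2]]$mgi)
  expect_lt(reps[[2]]$mgi, reps[[3]]$mgi)
  expect_lt(reps[[1]]$r50, reps[[2]]$r50)
  expect_lt(reps[[2]]$r50, reps[[3]]$r50)
})

test_that("empty prescription isodose is flagged, not crashed", {
  g <- image_grid(c(10, 10, 10), c(2, 2, 2))
  v <- array(FALSE, c(10, 10, 10)); v[4:6, 4:6, 4:6] <- TRUE
  tv <- binary_mask(v, g)
  body <- binary_mask(array(TRUE, c(10, 10, 10)), g)
  rep <- conformality_report(dose_grid(array(0.1, c(10, 10, 10)), g), 5,
                             tv, body)
  expect_true(rep$flags$piv_empty)
  expect_true(is.na(rep$mgi))
  expect_true(is.na(rep$paddick_ci))
})

test_that("reference limits interpolate and extrapolate linearly", {
  tab <- reference_limit_table(c(20, 40, 80), c(5, 4, 3.5))
  expect_equal(interpolate_limit(tab, 40), 4)
  expect_equal(interpolate_limit(tab, 30), 4.5)
  expect_equal(interpolate_limit(tab, 60), 3.75)
  # beyond the last knot: line through (40,4)-(80,3.5)
  expect_equal(interpolate_limit(tab, 120), 3.5 + 40 * (3.5 - 4) / 40)
  # before the first knot: line through (20,5)-(40,4)
  expect_equal(interpolate_limit(tab, 10), 5 + (10 - 20) * (4 - 5) / 20)
  expect_error(reference_limit_table(c(10), c(1)), "at least 2")
  expect_error(reference_limit_table(c(10, 10), c(1, 2)), "increasing")
})

test_that("the shipped protocol reference config loads and is ordered", {
  ref <- load_reference_limits()
  expect_named(ref, c("r50", "ntt_2cm"))
  for (m in ref) {
    expect_true(all(diff(m$none$ptv_cc) > 0))
    # the minor-deviation limit is never stricter than the no-deviation one
    expect_true(all(m$minor$limit >= m$none$limit))
  }
})
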