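# 3-D gamma-index comparison: identities, criteria monotonicity, and
# agreement with the exhaustive search.

test_that("identical distributions give gamma zero everywhere", {
  set.seed(50)
  p <- smooth_dose_pair(c(16, 16, 16), shift = c(0, 0, 0), scale = 1)
  res <- gamma_map(p$reference, p$reference,
                   gamma_criteria(2, 2, normalization = p$px))
  g <- res$gamma_field[!is.na(res$gamma_field)]
  expect_true(all(g == 0))
  expect_equal(res$pass_rate_pct, 100)
})

test_that("a uniform offset at exactly the criterion gives gamma one", {
  g <- image_grid(c(12, 12, 12), c(2, 2, 2))
  ref <- dose_grid(array(5, c(12, 12, 12)), g)
  ev <- dose_grid(array(5 + 0.02 * 5, c(12, 12, 12)), g)
  res <- gamma_map(ref, ev, gamma_criteria(2, 2, normalization = 5))
  gf <- res$gamma_field[!is.na(res$gamma_field)]
  expect_equal(max(abs(gf - 1)), 0, tolerance = 1e-9)
})

test_that("looser criteria never increase gamma; pass rates order", {
  set.seed(51)
  p <- smooth_dose_pair(c(20, 20, 20), shift = c(1.5, -1, 0.5),
                        scale = 1.015)
  g22 <- gamma_map(p$reference, p$evaluated,
                   gamma_criteria(2, 2, normalization = p$px))
  g33 <- gamma_map(p$reference, p$evaluated,
                   gamma_criteria(3, 3, normalization = p$px))
  d <- g33$gamma_field - g22$gamma_field
  expect_true(all(d[!is.na(d)] <= 1e-9))
  expect_gte(g33$pass_rate_pct, g22$pass_rate_pct)
})

test_that("optimized search agrees with the exhaustive brute force", {
  set.seed(52)
  p <- smooth_dose_pair(c(18, 18, 18), shift = c(1.2, 0.8, -0.6),
                        scale = 1.02)
  cr <- gamma_criteria(2, 2, normalization = p$px)
  fast <- gamma_map(p$reference, p$evaluated, cr)
  brute <- adcboost:::.gamma_brute_cpp(
    as.numeric(p$reference$values), as.numeric(p$evaluated$values),
    as.integer(p$grid$shape), as.numeric(p$grid$spacing),
    0.02, 2, p$px, FALSE, 0.1 * p$px, 6, cr$subsample_factor)
  diff <- abs(fast$gamma_field - array(brute, dim = p$grid$shape))
  expect_lt(max(diff[!is.na(diff)]), 1e-9)
})

test_that("both search paths match a plain-R reference on a tiny grid", {
  set.seed(53)
  sh <- c(7, 7, 7); sp <- c(2, 2, 2)
  g <- image_grid(sh, sp)
  ref <- array(runif(prod(sh), 1, 5), dim = sh)
  ev <- array(ref + rnorm(prod(sh), 0, 0.1), dim = sh)
  ev[ev < 0] <- 0
  dd <- 0.03 * 4; dta <- 3; radius <- 3; sub <- 2
  # plain-R exhaustive gamma with its own trilinear interpolation
  lin <- function(a, p) {
    i <- pmin(pmax(floor(p), 0), sh - 2)
    t <- p - i
    acc <- 0
    for (b1 in 0:1) for (b2 in 0:1) for (b3 in 0:1) {
      w <- prod(ifelse(c(b1, b2, b3) == 1, t, 1 - t))
      acc <- acc + w * a[i[1] + b1 + 1, i[2] + b2 + 1, i[3] + b3 + 1]
    }
    acc
  }
  ks <- seq(-radius, radius, by = sp[1] / sub)
  offs <- expand.grid(d1 = ks, d2 = ks, d3 = ks)
  offs <- offs[sqrt(rowSums(offs^2)) <= radius + 1e-9, ]
  gamma_r <- array(NA_real_, dim = sh)
  for (v in seq_len(prod(sh))) {
    idx <- arrayInd(v, sh)
    rd <- ref[v]
    if (rd < 0.4) next
    best <- Inf
    for (o in seq_len(nrow(offs))) {
      pos <- (idx - 1) + as.numeric(offs[o, ]) / sp
      if (any(pos < 0) || any(pos > sh - 1)) next
      e <- lin(ev, pos)
      gg <- (rd - e)^2 / dd^2 + sum(offs[o, ]^2) / dta^2
      if (gg < best) best <- gg
    }
    gamma_r[v] <- sqrt(best)
  }
  fast <- adcboost:::.gamma_search_cpp(as.numeric(ref), as.numeric(ev),
                                       as.integer(sh), as.numeric(sp),
                                       0.03, dta, 4, FALSE, 0.4, radius, sub)
  brute <- adcboost:::.gamma_brute_cpp(as.numeric(ref), as.numeric(ev),
                                       as.integer(sh), as.numeric(sp),
                                       0.03, dta, 4, FALSE, 0.4, radius, sub)
  expect_equal(array(fast, dim = sh), gamma_r, tolerance = 1e-9)
  expect_equal(array(brute, dim = sh), gamma_r, tolerance = 1e-9)
})

test_that("pass_rate restricts to a region and validates it", {
  g <- image_grid(c(8, 8, 8), c(2, 2, 2))
  ref <- dose_grid(array(5, c(8, 8, 8)), g)
  ev_v <- array(5, c(8, 8, 8)); ev_v[1:4, , ] <- 5.5   # 10% off: gamma > 1
  res <- gamma_map(ref, dose_grid(ev_v, g),
                   gamma_criteria(2, 2, normalization = 5,
                                  search_radius_factor = 0.4))
  expect_equal(res$pass_rate_pct, 50)
  lv <- array(FALSE, c(8, 8, 8)); lv[1:4, , ] <- TRUE
  left <- binary_mask(lv, g)
  right <- binary_mask(!lv, g)
  expect_lt(pass_rate(res, left), 50)
  expect_equal(pass_rate(res, right), 100)
})

test_that("growing rigid shifts degrade the 2%/2 mm pass rate", {
  set.seed(54)
  p1 <- smooth_dose_pair(c(20, 20, 20), shift = c(1, 0, 0), scale = 1)
  set.seed(54)
  p3 <- smooth_dose_pair(c(20, 20, 20), shift = c(3, 0, 0), scale = 1)
  cr <- gamma_criteria(2, 2, normalization = p1$px)
  r1 <- gamma_map(p1$reference, p1$evaluated, cr)$pass_rate_pct
  r3 <- gamma_map(p3$reference, p3$evaluated, cr)$pass_rate_pct
  expect_gt(r1, r3)
})

test_that("low-dose voxels are excluded and normalization is validated", {
  g <- image_grid(c(6, 6, 6), c(2, 2, 2))
  dv <- array(0.2, c(6, 6, 6)); dv[3, 3, 3] <- 5
  ref <- dose_grid(dv, g)
  res <- gamma_map(ref, ref, gamma_criteria(2, 2, normalization = 5))
  expect_equal(res$n_included, 1)
  expect_error(gamma_criteria(2, 2, normalization = 0))
  expect_error(gamma_map(ref, dose_grid(dv, image_grid(c(6, 6, 6),
                                                       c(1, 2, 2))),
                         gamma_criteria(2, 2, 5)), "mismatch")
})
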