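# Constraint classification, table evaluation, cohort tallies.

con <- function(direction, limit, variation = NULL, relative = FALSE) {
  list(direction = direction, limit = limit, variation = variation,
       relative_to_px = relative)
}

test_that("classify grades reported boost-plan violations correctly", {
  # conformality: spillage slightly over the clinical limit is minor
  expect_equal(classify(1.13, con("<", 1.10, 1.15))$status, "minor")
  expect_equal(classify(4.88, con("<", 4.5, 5))$status, "minor")
  # nucleus coverage just under prescription: binary constraint, major
  expect_equal(classify(4.93, con(">", 100, relative = TRUE), px = 5)$status,
               "major")
  expect_equal(classify(4.86, con(">", 100, relative = TRUE), px = 5)$status,
               "major")
  # bladder mean dose over 35% of a 5 Gy prescription
  expect_equal(classify(1.90, con("<", 35, relative = TRUE), px = 5)$status,
               "major")
  expect_equal(classify(1.90, con("<", 35, relative = TRUE),
                        px = 5)$limit_abs, 1.75)
})

test_that("equality meets a strict printed limit on the permissive side", {
  expect_equal(classify(1.10, con("<", 1.10, 1.15))$status, "optimal")
  expect_equal(classify(1.15, con("<", 1.10, 1.15))$status, "minor")
  expect_equal(classify(5.0, con(">", 100, relative = TRUE), px = 5)$status,
               "optimal")
})

test_that("classify is monotone and partitions the line", {
  cc <- con("<", 10, 12)
  statuses <- vapply(seq(8, 14, by = 0.25),
                     function(v) classify(v, cc)$status, character(1))
  ranks <- c(optimal = 1, minor = 2, major = 3)[statuses]
  expect_true(all(diff(ranks) >= 0))
  expect_setequal(unique(statuses), c("optimal", "minor", "major"))
  # reversed direction
  cg <- con(">", 10, 8)
  ranks2 <- c(optimal = 1, minor = 2, major = 3)[
    vapply(seq(12, 6, by = -0.25), function(v) classify(v, cg)$status,
           character(1))]
  expect_true(all(diff(ranks2) >= 0))
})

test_that("fractional variation grades OAR exceedances", {
  cc <- con("<", 20)
  expect_equal(classify(20, cc, variation_fraction = 0.1)$status, "optimal")
  expect_equal(classify(21.9, cc, variation_fraction = 0.1)$status, "minor")
  expect_equal(classify(22.1, cc, variation_fraction = 0.1)$status, "major")
  # without any variation the constraint is binary
  expect_equal(classify(20.01, cc)$status, "major")
})

test_that("misconfigured variation on the strict side is rejected", {
  expect_error(classify(1, con("<", 10, 8)), "permissive")
  expect_error(classify(1, con(">", 10, 12)), "permissive")
  expect_error(classify(Inf, con("<", 1)), "finite")
  expect_error(classify(1, con(">", 100, relative = TRUE)), "px")
})

compliant_phase1_fixture <- function(seed = 9) {
  ph <- generate_phantom(phantom_spec(), seed = seed)
  bs <- delineate_boost(ph$adc, ph$structures$gtv, ph$structures$ctv)
  dose <- analytic_dose(bs$btv, dose_model(
    5, plateau_level = 1.01, falloff_half_distance = 5,
    hotspot = list(center = centroid_mm(bs$c40), peak = 1.12,
                   sigma_mm = 5)))
  list(dose = dose,
       structures = list(c40 = bs$c40, btv = bs$btv,
                         eval = bs$eval_structure,
                         body = ph$structures$body,
                         bladder = ph$structures$bladder))
}

test_that("a constructed compliant boost field passes every mandatory row", {
  fx <- compliant_phase1_fixture()
  res <- evaluate_phase1(fx$dose, fx$structures, px = 5)
  expect_equal(nrow(res), 14)     # one row per shipped constraint
  mand <- res[res$tier == "mandatory", ]
  expect_true(all(mand$status == "optimal"))
  # every configured row mapped to exactly one evaluated metric
  cfg <- load_constraints("phase1")
  expect_equal(nrow(res), length(cfg$constraints))
  expect_false(any(duplicated(paste(res$structure, res$metric))))
})

test_that("a pathological uniform field fails spillage grossly", {
  fx <- compliant_phase1_fixture()
  flat <- dose_grid(array(5, dim = fx$dose$grid$shape), fx$dose$grid)
  res <- evaluate_phase1(flat, fx$structures, px = 5)
  expect_equal(res$status[res$metric == "PDS"], "major")
  expect_equal(res$status[res$metric == "NTT"], "major")
  # EVAL sees no overdose from a field at exactly the prescription
  expect_equal(res$value[res$metric == "V110%px"], 0)
  expect_error(evaluate_phase1(flat, fx$structures[-1], px = 5), "c40")
})

test_that("combined evaluation flags a half-irradiated bladder", {
  g <- image_grid(c(20, 20, 20), c(2, 2, 2))
  full <- binary_mask(array(TRUE, c(20, 20, 20)), g)
  vb <- array(FALSE, c(20, 20, 20)); vb[5:12, 5:12, 5:12] <- TRUE
  bladder <- binary_mask(vb, g)
  dv <- array(0, c(20, 20, 20)); dv[5:12, 5:12, 1:20] <- 0
  dv[vb] <- rep(c(46, 0), length.out = sum(vb))   # half the bladder at 46 Gy
  structures <- list(bladder = bladder, bowel_cavity = full,
                     large_bowel = bladder, small_bowel = bladder,
                     ptv4500 = full, ptv5000 = full)
  res <- evaluate_combined(dose_grid(dv, g), structures)
  v45 <- res[res$structure == "bladder" & res$metric == "V45Gy", ]
  expect_equal(v45$value, 50)
  expect_equal(v45$status, "major")
  # zero dose: all OAR rows optimal, volume metrics zero
  res0 <- evaluate_combined(dose_grid(array(0, c(20, 20, 20)), g),
                            structures)
  oar <- res0[res0$status != "reported", ]
  expect_true(all(oar$status == "optimal"))
  expect_true(all(oar$value[grepl("^V", oar$metric)] == 0))
  expect_equal(nrow(res0), length(load_constraints("combined")$constraints))
})

test_that("tally computes interpolated quartiles and violation counts", {
  mk <- function(value, status) {
    data.frame(structure = "bladder", metric = "V45Gy", tier = "oar",
               value = value, limit = 15, variation = 16.5,
               direction = "<", status = status, stringsAsFactors = FALSE)
  }
  plans <- lapply(1:5, function(i) {
    mk(i, c("optimal", "minor", "major", "optimal", "minor")[i])
  })
  tl <- tally(plans)
  expect_equal(tl$median, 3)
  expect_equal(tl$iqr, 2)
  expect_equal(tl$minor, 2)
  expect_equal(tl$major, 1)
  expect_equal(tl$n, 5)
  # single plan: IQR zero
  t1 <- tally(plans[3])
  expect_equal(t1$iqr, 0)
  expect_equal(t1$median, 3)
  # permutation invariance
  t_perm <- tally(plans[c(4, 2, 5, 1, 3)])
  expect_equal(t_perm$median, tl$median)
  expect_equal(t_perm$minor, tl$minor)
  expect_error(tally(list()), "no plans")
})
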