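# End-to-end study runner: delineation -> phase-1 evaluation -> combined
# evaluation -> gamma QA -> cohort summaries, with deterministic outputs.

#' Configuration of a full phantom study
#'
#' @param preset phantom preset, \code{"compliant"} or \code{"stressed"}.
#' @param n number of subjects.
#' @param boost_px boost prescription levels in Gy.
#' @param conventional_px long-course prescription in Gy.
#' @param centile ADC percentile for subvolume segmentation.
#' @param gamma_criteria list of \code{c(dose_diff_pct, dta_mm)} pairs
#'   evaluated per boost plan (default 2%/2 mm and 3%/3 mm).
#' @param qa_shift_mm,qa_scale,qa_noise_sd perturbation applied to the
#'   planned boost dose to form the evaluated distribution of the
#'   computational QA comparison.
#' @param out_dir optional output directory; when NULL nothing is written.
#' @param seed top-level seed; every random stage derives from it.
#' @param constraints_phase1,constraints_combined constraint-set paths or
#'   the packaged shorthands.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(preset = "compliant", n = 10,
                       boost_px = c(5, 7, 10), conventional_px = 50,
                       centile = 40,
                       gamma_criteria = list(c(2, 2), c(3, 3)),
                       qa_shift_mm = c(0.5, 0.5, 0), qa_scale = 1.005,
                       qa_noise_sd = 0,
                       out_dir = NULL, seed = 1,
                       constraints_phase1 = "phase1",
                       constraints_combined = "combined") {
  if (any(boost_px <= 0) || conventional_px <= 0)
    stop("prescription doses must be > 0")
  structure(list(preset = preset, n = n, boost_px = boost_px,
                 conventional_px = conventional_px, centile = centile,
                 gamma_criteria = gamma_criteria,
                 qa_shift_mm = qa_shift_mm, qa_scale = qa_scale,
                 qa_noise_sd = qa_noise_sd,
                 out_dir = out_dir, seed = seed,
                 constraints_phase1 = constraints_phase1,
                 constraints_combined = constraints_combined),
            class = "run_config")
}

config_hash <- function(config) {
  plain <- config[setdiff(names(config), "out_dir")]
  f <- tempfile()
  on.exit(unlink(f))
  jsonlite::write_json(plain, f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

#' Run the full study on a phantom cohort
#'
#' Generates (or reuses) a seeded cohort, then per subject: delineates the
#' boost structures once, evaluates the phase-1 constraint set at every
#' boost level, evaluates the combined constraint set on each summed
#' dose, and runs the gamma QA comparison of the planned boost dose
#' against its perturbed copy at every configured criteria pair. Cohort
#' summaries (median, IQR, minor/major counts) are tallied per dose
#' level. Deterministic given the seed.
#'
#' @param config a \code{\link{run_config}}.
#' @param cohort optional pre-built \code{\link{generate_cohort}} result
#'   (must match the config's seed/preset to stay reproducible).
#' @return list of class \code{study_report}: per-plan results, cohort
#'   summaries, gamma reports, provenance.
#' @export
run_study <- function(config = run_config(), cohort = NULL) {
  cfg_p1 <- load_constraints(config$constraints_phase1)
  cfg_comb <- load_constraints(config$constraints_combined)
  ref <- load_reference_limits()
  if (is.null(cohort))
    cohort <- generate_cohort(config$n, phantom_spec(config$preset),
                              seed = config$seed,
                              boost_px = config$boost_px,
                              conventional_px = config$conventional_px)
  lvl <- paste0(config$boost_px, "Gy")
  phase1 <- setNames(vector("list", length(lvl)), lvl)
  combined <- setNames(vector("list", length(lvl)), lvl)
  gamma <- setNames(vector("list", length(lvl)), lvl)
  for (k in seq_along(lvl)) {
    phase1[[k]] <- vector("list", length(cohort$subjects))
    combined[[k]] <- vector("list", length(cohort$subjects))
    gamma[[k]] <- vector("list", length(cohort$subjects))
  }
  for (i in seq_along(cohort$subjects)) {
    su <- cohort$subjects[[i]]
    st1 <- list(c40 = su$boost$c40, btv = su$boost$btv,
                eval = su$boost$eval_structure,
                body = su$phantom$structures$body,
                bladder = su$phantom$structures$bladder)
    st2 <- list(bladder = su$phantom$structures$bladder,
                bowel_cavity = su$phantom$structures$bowel_cavity,
                large_bowel = su$phantom$structures$large_bowel,
                small_bowel = su$phantom$structures$small_bowel,
                ptv4500 = su$ptv4500,
                ptv5000 = su$phantom$structures$ptv)
    for (k in seq_along(lvl)) {
      px <- config$boost_px[k]
      bd <- su$doses$boost[[k]]
      phase1[[k]][[i]] <- evaluate_phase1(bd, st1, px, cfg_p1, ref)
      combined[[k]][[i]] <- evaluate_combined(
        su$doses$summed[[k]], st2, cfg_comb,
        conventional_dose = su$doses$conventional)
      qa <- perturb_dose(bd, shift_mm = config$qa_shift_mm,
                         scale = config$qa_scale,
                         noise_sd = config$qa_noise_sd,
                         seed = config$seed + 37L * i + k)
      gamma[[k]][[i]] <- lapply(config$gamma_criteria, function(cr) {
        gamma_report(gamma_map(bd, qa,
                               gamma_criteria(cr[1], cr[2],
                                              normalization = px)))
      })
    }
  }
  report <- structure(list(
    phase1 = phase1, combined = combined, gamma = gamma,
    phase1_summary = lapply(phase1, tally),
    combined_summary = lapply(combined, tally),
    provenance = list(config_hash = config_hash(config),
                      seed = config$seed, preset = cohort$preset,
                      n_subjects = length(cohort$subjects),
                      package_version = as.character(
                        packageVersion("adcboost")))),
    class = "study_report")
  if (!is.null(config$out_dir)) write_study_report(report, config$out_dir)
  report
}

#' Count violations in a study report
#'
#' @param report a \code{\link{run_study}} result.
#' @param which \code{"phase1"} or \code{"combined"}.
#' @param tier optional tier filter (e.g. \code{"mandatory"}).
#' @return data.frame of minor/major counts per dose level.
#' @export
count_violations <- function(report, which = c("phase1", "combined"),
                             tier = NULL) {
  which <- match.arg(which)
  per_level <- report[[which]]
  rows <- lapply(names(per_level), function(lv) {
    all <- do.call(rbind, per_level[[lv]])
    if (!is.null(tier)) all <- all[all$tier == tier, ]
    data.frame(level = lv, minor = sum(all$status == "minor"),
               major = sum(all$status == "major"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a study report to disk
#'
#' Layout: \code{summary/} holds the per-level cohort CSVs mirroring the
#' phase-1 and combined constraint tables plus a provenance JSON;
#' \code{plans/} holds one CSV per subject x level x table.
#'
#' @param report a \code{\link{run_study}} result.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_study_report <- function(report, dir) {
  sdir <- file.path(dir, "summary")
  pdir <- file.path(dir, "plans")
  dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
  for (lv in names(report$phase1_summary)) {
    write.csv(report$phase1_summary[[lv]],
              file.path(sdir, sprintf("phase1_%s.csv", lv)),
              row.names = FALSE)
    write.csv(report$combined_summary[[lv]],
              file.path(sdir, sprintf("combined_%s.csv", lv)),
              row.names = FALSE)
    for (i in seq_along(report$phase1[[lv]])) {
      write.csv(report$phase1[[lv]][[i]],
                file.path(pdir, sprintf("subject%02d_phase1_%s.csv", i, lv)),
                row.names = FALSE)
      write.csv(report$combined[[lv]][[i]],
                file.path(pdir, sprintf("subject%02d_combined_%s.csv", i, lv)),
                row.names = FALSE)
    }
  }
  jsonlite::write_json(report$gamma, file.path(sdir, "gamma.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(report$provenance,
                       file.path(sdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>", x$provenance$n_subjects, "subjects, preset",
      x$provenance$preset, "\n")
  cat("phase-1 mandatory violations:\n")
  print(count_violations(x, "phase1", tier = "mandatory"))
  cat("combined-plan violations:\n")
  print(count_violations(x, "combined"))
  invisible(x)
}
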