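# Constraint engine: encode the boost-phase and combined-plan dose
# constraint sets, classify metric values as optimal / minor violation /
# major violation, and tally cohort summaries.

#' Load a constraint set from YAML
#'
#' Shipped defaults: \code{phase1_table1.yaml} (single-fraction boost) and
#' \code{combined_table4.yaml} (summed boost + long-course plan).
#'
#' @param path YAML file, or one of the shorthand names \code{"phase1"} /
#'   \code{"combined"} for the packaged defaults.
#' @return list of class \code{constraint_set}.
#' @export
load_constraints <- function(path = "phase1") {
  if (path %in% c("phase1", "combined")) {
    fname <- c(phase1 = "phase1_table1.yaml",
               combined = "combined_table4.yaml")[[path]]
    path <- system.file("extdata", fname, package = "adcboost")
  }
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "constraint_set")
}

#' Classify a metric value against a constraint
#'
#' Limits are strict inequalities as printed; equality counts as meeting
#' the limit on the permissive side. A value meeting the primary limit is
#' \code{optimal}; failing it but meeting the acceptable variation is a
#' \code{minor} violation; anything else is \code{major}. Constraints
#' without an acceptable variation are binary (optimal/major).
#'
#' @param value measured metric value (finite).
#' @param constraint a single constraint row (named list with
#'   \code{direction}, \code{limit}, optional \code{variation},
#'   \code{relative_to_px}).
#' @param px prescription dose in Gy; required when the limit is a
#'   percentage of the prescription.
#' @param variation_fraction optional default fractional tolerance: when
#'   the row has no explicit variation, an exceedance within this fraction
#'   of the limit is graded minor.
#' @return list with \code{status} (\code{"optimal"}, \code{"minor"},
#'   \code{"major"}), \code{limit_abs} and \code{variation_abs}.
#' @export
classify <- function(value, constraint, px = NULL,
                     variation_fraction = NULL) {
  if (!is.finite(value)) stop("metric value must be finite")
  dir <- constraint$direction
  if (!dir %in% c("<", ">")) stop("constraint direction must be '<' or '>'")
  rel <- isTRUE(constraint$relative_to_px)
  if (rel && (is.null(px) || px <= 0))
    stop("px must be > 0 for prescription-relative constraints")
  scale <- if (rel) px / 100 else 1
  limit <- constraint$limit * scale
  variation <- if (!is.null(constraint$variation))
    constraint$variation * scale
  else if (!is.null(variation_fraction)) {
    if (dir == "<") limit * (1 + variation_fraction)
    else limit * (1 - variation_fraction)
  } else NA_real_
  if (!is.na(variation)) {
    ok <- if (dir == "<") variation >= limit else variation <= limit
    if (!ok) stop("acceptable variation must be on the permissive side of the limit")
  }
  meets <- function(lim) if (dir == "<") value <= lim else value >= lim
  status <- if (meets(limit)) "optimal"
            else if (!is.na(variation) && meets(variation)) "minor"
            else "major"
  list(status = status, limit_abs = limit, variation_abs = variation)
}

# measure one configured metric on a dose grid
eval_metric <- function(con, dose, structures, dvh_cache, conf = NULL) {
  kind <- con$kind
  if (kind == "conformality") {
    if (is.null(conf)) stop("conformality metrics need a conformality report")
    return(conf[[con$key]])
  }
  key <- con$structure
  st <- structures[[key]]
  if (is.null(st))
    stop(sprintf("structure '%s' required by constraint '%s %s' is missing",
                 key, con$structure, con$metric))
  switch(kind,
    dose_pct = {
      dv <- get0(key, envir = dvh_cache)
      if (is.null(dv)) {
        dv <- cumulative_dvh(dose, st)
        assign(key, dv, envir = dvh_cache)
      }
      dose_at_relative_volume(dv, con$pct)
    },
    dose_cc = dose_to_hottest_cc(dose, st, con$cc),
    dmean = mean_dose(dose, st),
    dmax = max_dose(dose, st),
    vol_at_dose = volume_at_dose(dose, st, con$level_Gy, con$mode),
    stop("unknown constraint kind: ", kind))
}

result_row <- function(con, value, cls, status) {
  data.frame(structure = con$structure, metric = con$metric,
             tier = if (is.null(con$tier)) "oar" else con$tier,
             value = value,
             limit = if (is.null(cls)) NA_real_ else cls$limit_abs,
             variation = if (is.null(cls)) NA_real_ else cls$variation_abs,
             direction = if (is.null(con$direction)) "" else con$direction,
             status = status, stringsAsFactors = FALSE)
}

#' Evaluate the phase-1 boost constraint set
#'
#' Audits a single-fraction boost dose against every row of the boost
#' constraint table: C40/BTV coverage and hotspot rows, the EVAL fall-off
#' shell, the PDS/MGI conformality constraints, and the secondary
#' R50/NTT_2cm (limits interpolated from the protocol reference table by
#' PTV volume), NTT and bladder mean-dose rows.
#'
#' @param boost_dose \code{\link{dose_grid}} of the boost phase.
#' @param structures named list with \code{c40}, \code{btv}, \code{eval},
#'   \code{body}, \code{bladder}, and optionally \code{ptv} (defaults to
#'   the BTV, which is the boost planning target here).
#' @param px boost prescription dose in Gy.
#' @param config a \code{\link{load_constraints}} result (default:
#'   packaged phase-1 table).
#' @param ref_limits reference limit tables from
#'   \code{\link{load_reference_limits}}.
#' @return \code{data.frame} with one row per constraint (value, absolute
#'   limit, status), plus the conformality report as attribute
#'   \code{"conformality"}.
#' @export
evaluate_phase1 <- function(boost_dose, structures, px,
                            config = load_constraints("phase1"),
                            ref_limits = load_reference_limits()) {
  for (need in c("c40", "btv", "eval", "body", "bladder")) {
    if (is.null(structures[[need]]))
      stop(sprintf("required structure '%s' is missing", need))
  }
  if (is.null(structures$ptv)) structures$ptv <- structures$btv
  conf <- conformality_report(boost_dose, px, tv = structures$btv,
                              body = structures$body, ptv = structures$ptv,
                              bladder = structures$bladder)
  dvh_cache <- new.env(parent = emptyenv())
  rows <- lapply(config$constraints, function(con) {
    # EVAL may legitimately be empty (tight BTV): zero spill by definition
    if (con$structure == "eval" && !sum(structures$eval$voxels)) {
      value <- 0
    } else if (con$kind == "vol_at_rel_dose") {
      value <- volume_at_dose(boost_dose, structures[[con$structure]],
                              con$level_pct_px / 100 * px, con$mode)
    } else {
      value <- eval_metric(con, boost_dose, structures, dvh_cache, conf)
    }
    if (identical(con$limit, "reference")) {
      tab <- ref_limits[[con$reference]]
      con$limit <- interpolate_limit(tab$none, conf$ptv_cc)
      con$variation <- interpolate_limit(tab$minor, conf$ptv_cc)
    }
    if (is.na(value)) return(result_row(con, value, NULL, "undefined"))
    cls <- classify(value, con, px)
    result_row(con, value, cls, cls$status)
  })
  out <- do.call(rbind, rows)
  attr(out, "conformality") <- conf
  attr(out, "px") <- px
  class(out) <- c("constraint_results", class(out))
  out
}

#' Evaluate the combined-plan constraint set on a summed dose
#'
#' Audits the physical sum of the boost and long-course phases against the
#' combined-plan table: bladder V40/V45/Dmax, bowel-cavity V45 and D1cc,
#' large-bowel V30/V35/V45, small-bowel V15/D1cc, plus PTV coverage rows
#' reported without a violation status. OAR rows without an explicit
#' acceptable variation use the fractional minor/major boundary in the
#' config (\code{variation_fraction}, default 10% of the limit).
#'
#' @param summed_dose \code{\link{dose_grid}} of the summed phases.
#' @param structures named list of OAR and PTV \code{binary_mask}s keyed
#'   as in the config (\code{bladder}, \code{bowel_cavity},
#'   \code{large_bowel}, \code{small_bowel}, \code{ptv4500},
#'   \code{ptv5000}).
#' @param config a \code{\link{load_constraints}} result (default:
#'   packaged combined table).
#' @param conventional_dose optional \code{dose_grid} of the long-course
#'   phase alone; rows flagged \code{phase2_only} (the PTV coverage rows,
#'   whose targets belong to the conventional phase) are measured on it
#'   when supplied, otherwise on the summed dose.
#' @return \code{data.frame} of class \code{constraint_results}.
#' @export
evaluate_combined <- function(summed_dose, structures,
                              config = load_constraints("combined"),
                              conventional_dose = NULL) {
  vf <- if (is.null(config$variation_fraction)) 0.10
        else config$variation_fraction
  dvh_cache <- new.env(parent = emptyenv())
  dvh_cache_p2 <- new.env(parent = emptyenv())
  rows <- lapply(config$constraints, function(con) {
    use_p2 <- isTRUE(con$phase2_only) && !is.null(conventional_dose)
    value <- eval_metric(con,
                         if (use_p2) conventional_dose else summed_dose,
                         structures,
                         if (use_p2) dvh_cache_p2 else dvh_cache)
    if (isTRUE(con$report_only)) {
      if (identical(con$report, "pct_of_phase_px"))
        value <- 100 * value / con$phase_px
      else if (identical(con$report, "excess_pct_of_phase_px"))
        value <- 100 * (value / con$phase_px - 1)
      return(result_row(con, value, NULL, "reported"))
    }
    cls <- classify(value, con, variation_fraction = vf)
    result_row(con, value, cls, cls$status)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("constraint_results", class(out))
  out
}

#' Cohort summary of constraint results
#'
#' Per-constraint median and interquartile range of the measured values
#' (quartiles by linear interpolation) and counts of minor and major
#' violations over a set of plans.
#'
#' @param results list of \code{constraint_results} data frames, one per
#'   plan.
#' @return \code{data.frame} with one row per constraint: median, IQR,
#'   minor and major counts, cohort size.
#' @export
tally <- function(results) {
  if (!length(results)) stop("no plans to tally")
  all <- do.call(rbind, Map(function(df, i) {
    df$plan <- i; df
  }, results, seq_along(results)))
  keys <- unique(all[, c("structure", "metric", "tier")])
  rows <- lapply(seq_len(nrow(keys)), function(k) {
    sel <- all$structure == keys$structure[k] & all$metric == keys$metric[k]
    v <- all$value[sel]
    data.frame(structure = keys$structure[k], metric = keys$metric[k],
               tier = keys$tier[k],
               median = median(v, na.rm = TRUE),
               iqr = unname(diff(quantile(v, c(0.25, 0.75), type = 7,
                                          na.rm = TRUE))),
               minor = sum(all$status[sel] == "minor"),
               major = sum(all$status[sel] == "major"),
               n = sum(sel), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_summary", class(out))
  out
}
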