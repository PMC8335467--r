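#' Construct a dose criterion
#'
#' A criterion is either a volume-at-dose constraint `V_<dose Gy>` (in cc or
#' % of the structure) or a dose-at-volume constraint `D_<p %>` (Gy), with an
#' upper (`<`) or lower (`>=`) bound, an optional minor-variation band on the
#' failing side, and a flag marking membership in the penalty score.
#'
#' @param id short identifier, e.g. `"V37Gy_bladder"`.
#' @param structure structure name as present in the structure set.
#' @param metric `"V"` or `"D"`.
#' @param dose_gy threshold dose for `V` metrics (NA for `D`).
#' @param volume_pct volume level for `D` metrics (NA for `V`).
#' @param unit `"cc"` or `"pct"` for `V`; `"Gy"` for `D`.
#' @param direction `"upper"` (value must stay below the bound) or `"lower"`.
#' @param bound the constraint value C (> 0).
#' @param minor_lo,minor_hi optional minor-variation band limits.
#' @param in_penalty logical; whether violations contribute to S.
#' @return one-row data.frame of class `dose_criterion`.
#' @export
dose_criterion <- function(id, structure, metric, dose_gy = NA,
                           volume_pct = NA, unit, direction, bound,
                           minor_lo = NA, minor_hi = NA, in_penalty = FALSE) {
  metric <- match.arg(metric, c("V", "D"))
  direction <- match.arg(direction, c("upper", "lower"))
  if (!is.finite(bound) || bound <= 0)
    stop("criterion bound must be positive (required by the relative penalty)")
  if (!is.na(minor_lo) && direction == "lower" && minor_lo > bound)
    stop("minor band must lie on the failing side of the bound")
  if (!is.na(minor_hi) && direction == "upper" && minor_hi < bound)
    stop("minor band must lie on the failing side of the bound")
  out <- data.frame(id = id, structure = structure, metric = metric,
                    dose_gy = as.numeric(dose_gy),
                    volume_pct = as.numeric(volume_pct), unit = unit,
                    direction = direction, bound = bound,
                    minor_lo = as.numeric(minor_lo),
                    minor_hi = as.numeric(minor_hi),
                    in_penalty = in_penalty,
                    stringsAsFactors = FALSE)
  class(out) <- c("dose_criterion", class(out))
  out
}

#' The PACE-C criterion table
#'
#' Reads the shipped criterion configuration: the full PACE-C constraint set
#' (target coverage with minor-variation bands, rectum, bladder, bowel,
#' femoral heads, penile bulb) with `in_penalty = TRUE` for the four scored
#' criteria V36.25Gy(PTV), D98%(PTV), V37Gy(bladder) and V36Gy(rectum).
#'
#' @param file optional path to an alternative criterion CSV.
#' @return data.frame with one row per criterion.
#' @export
pace_criteria <- function(file = NULL) {
  file <- file %||% system.file("extdata", "pace_criteria.csv",
                                package = "adaptrt", mustWork = TRUE)
  cr <- read.csv(file, stringsAsFactors = FALSE)
  needed <- c("id", "structure", "metric", "dose_gy", "volume_pct", "unit",
              "direction", "bound", "minor_lo", "minor_hi", "in_penalty")
  if (!all(needed %in% names(cr)))
    stop("malformed criteria file: missing column(s) ",
         paste(setdiff(needed, names(cr)), collapse = ", "))
  if (any(cr$bound <= 0)) stop("criteria file contains a non-positive bound")
  cr$in_penalty <- as.logical(cr$in_penalty)
  cr
}

# the four scored criteria; V40Gy(CTV) is always excluded from S
penalty_criterion_ids <- function()
  c("V36.25Gy_PTV", "D98pct_PTV", "V37Gy_bladder", "V36Gy_rectum")

#' Relative penalty of one constraint
#'
#' `|(M - C)/C| * 100` when the criterion is exceeded (strictly beyond the
#' bound: `M > C` for upper, `M < C` for lower), else 0. `M = C` exactly is
#' not exceeded.
#'
#' @param M measured metric value.
#' @param C constraint value (> 0).
#' @param direction `"upper"` or `"lower"`.
#' @return dimensionless penalty >= 0.
#' @export
penalty_score <- function(M, C, direction = c("upper", "lower")) {
  direction <- match.arg(direction)
  if (!is.finite(C) || C <= 0)
    stop("constraint value C must be positive")
  exceeded <- if (direction == "upper") M > C else M < C
  if (exceeded) abs((M - C) / C) * 100 else 0
}

measure_criterion <- function(dose, structures, cr) {
  mask <- structures$masks[[cr$structure]]
  if (is.null(mask))
    stop("structure '", cr$structure, "' missing from the structure set")
  if (cr$metric == "V") {
    mode <- if (cr$unit == "cc") "absolute" else "relative"
    v_dose(dose, mask, cr$dose_gy, mode)
  } else {
    d_volume(dose, mask, cr$volume_pct)
  }
}

#' Evaluate one criterion on one plan
#'
#' Computes the metric voxel-exactly, assigns the tier (`optimal` when the
#' bound is met, `minor` when exceeded but inside the minor-variation band,
#' else `violation`) and the penalty contribution.
#'
#' @param dose a [dose_grid()].
#' @param structures a [structure_set()].
#' @param criterion one criterion row ([dose_criterion()] or a
#'   [pace_criteria()] row).
#' @return one-row data.frame: id, structure, measured, bound, direction,
#'   tier, penalty, in_penalty.
#' @export
evaluate_criterion <- function(dose, structures, criterion) {
  cr <- as.list(criterion)
  M <- measure_criterion(dose, structures, cr)
  pen <- penalty_score(M, cr$bound, cr$direction)
  exceeded <- pen > 0
  tier <- if (!exceeded) "optimal"
    else if (cr$direction == "lower" && !is.na(cr$minor_lo) && M >= cr$minor_lo) "minor"
    else if (cr$direction == "upper" && !is.na(cr$minor_hi) && M <= cr$minor_hi) "minor"
    else "violation"
  data.frame(id = cr$id, structure = cr$structure, measured = M,
             bound = cr$bound, direction = cr$direction, tier = tier,
             penalty = pen, in_penalty = cr$in_penalty,
             stringsAsFactors = FALSE)
}

#' Total penalty S of one plan
#'
#' Sum of the contributions of the four scored criteria; V40Gy(CTV) and all
#' reporting-only criteria never contribute.
#'
#' @param results data.frame of [evaluate_criterion()] rows.
#' @return scalar S >= 0.
#' @export
plan_penalty <- function(results) {
  need <- penalty_criterion_ids()
  have <- results$id[results$in_penalty]
  if (!all(need %in% have))
    stop("missing scored criterion result(s): ",
         paste(setdiff(need, have), collapse = ", "))
  sum(results$penalty[results$in_penalty & results$id %in% need])
}

#' Evaluate one plan against a criterion table
#'
#' Evaluates every criterion whose structure is present in the set (the full
#' PACE-C table includes organs the synthetic cohort does not model; those
#' rows are skipped), computes the total penalty S and the PTV-OAR overlap
#' volumes.
#'
#' @param dose a [dose_grid()].
#' @param structures the daily [structure_set()].
#' @param criteria criterion table (default [pace_criteria()]).
#' @param patient,fraction,approach labels attached to the result.
#' @return object of class `plan_evaluation`: labels, `results` data.frame,
#'   `overlap_bladder_cc`, `overlap_rectum_cc`, `S`.
#' @export
evaluate_plan <- function(dose, structures, criteria = pace_criteria(),
                          patient = "P1", fraction = 1L,
                          approach = "REFERENCE") {
  avail <- criteria[criteria$structure %in% names(structures$masks), ]
  res <- do.call(rbind, lapply(seq_len(nrow(avail)), function(i)
    evaluate_criterion(dose, structures, avail[i, ])))
  ov_b <- overlap_volume(structures$masks$ptv, structures$masks$bladder,
                         structures$grid)
  ov_r <- overlap_volume(structures$masks$ptv, structures$masks$rectum,
                         structures$grid)
  structure(list(patient = patient, fraction = as.integer(fraction),
                 approach = approach, results = res,
                 overlap_bladder_cc = ov_b, overlap_rectum_cc = ov_r,
                 S = plan_penalty(res)),
            class = "plan_evaluation")
}

#' @export
print.plan_evaluation <- function(x, ...) {
  cat(sprintf("<plan_evaluation> %s fraction %d %s: S = %.3f (%d criteria, %d violated)\n",
              x$patient, x$fraction, x$approach, x$S, nrow(x$results),
              sum(x$results$tier != "optimal")))
  invisible(x)
}

#' Flatten plan evaluations to a tidy table
#'
#' @param evaluations list of `plan_evaluation` objects.
#' @return data.frame with one row per plan-criterion, carrying the plan
#'   total S and overlap volumes on every row.
#' @export
evaluations_to_df <- function(evaluations) {
  do.call(rbind, lapply(evaluations, function(ev) {
    df <- ev$results
    df$patient <- ev$patient
    df$fraction <- ev$fraction
    df$approach <- ev$approach
    df$S <- ev$S
    df$overlap_bladder_cc <- ev$overlap_bladder_cc
    df$overlap_rectum_cc <- ev$overlap_rectum_cc
    df
  }))
}

#' Cohort penalty aggregation (Table-3 twin)
#'
#' Produces both summations of the penalty score: per dose criterion summed
#' over all plans of an approach (inter-modality comparison) and per patient
#' as mean +/- sample SD over the fraction plans (inter-patient comparison),
#' plus column totals and the cohort mean of the per-patient means.
#'
#' @param evaluations list of `plan_evaluation` objects or a tidy data.frame
#'   from [evaluations_to_df()], covering a full patients x fractions x
#'   approaches grid.
#' @return object of class `penalty_table`: `per_criterion` (criterion x
#'   approach sums), `totals`, `per_patient` (mean, sd per patient x
#'   approach), `cohort_mean`, `cohort_sd`.
#' @export
cohort_penalty_table <- function(evaluations) {
  df <- if (is.data.frame(evaluations)) evaluations
        else evaluations_to_df(evaluations)
  df <- df[df$in_penalty, ]
  # every plan must carry the same criterion rows over a complete grid
  cnt <- table(paste(df$patient, df$fraction, df$approach))
  n_cells <- length(unique(df$patient)) * length(unique(df$fraction)) *
             length(unique(df$approach))
  if (length(unique(as.vector(cnt))) != 1 || length(cnt) != n_cells)
    stop("evaluations do not cover a full patients x fractions x approaches grid")

  approaches <- intersect(approach_kinds(), unique(df$approach))
  ids <- penalty_criterion_ids()
  per_criterion <- sapply(approaches, function(a)
    sapply(ids, function(i) sum(df$penalty[df$approach == a & df$id == i])))
  per_criterion <- matrix(per_criterion, nrow = length(ids),
                          dimnames = list(ids, approaches))
  totals <- colSums(per_criterion)

  plans <- unique(df[c("patient", "fraction", "approach", "S")])
  patients <- unique(plans$patient)
  agg <- function(f) sapply(approaches, function(a)
    sapply(patients, function(p)
      f(plans$S[plans$patient == p & plans$approach == a])))
  pmean <- matrix(agg(mean), nrow = length(patients),
                  dimnames = list(patients, approaches))
  # sample SD over the fraction plans; 0 by convention for n = 1
  psd <- matrix(agg(function(s) if (length(s) > 1) sd(s) else 0),
                nrow = length(patients),
                dimnames = list(patients, approaches))

  structure(list(per_criterion = per_criterion, totals = totals,
                 per_patient_mean = pmean, per_patient_sd = psd,
                 cohort_mean = colMeans(pmean),
                 cohort_sd = apply(pmean, 2, sd)),
            class = "penalty_table")
}

#' @export
print.penalty_table <- function(x, ...) {
  cat("<penalty_table> per-criterion sums:\n")
  print(round(x$per_criterion, 1))
  cat("totals:\n")
  print(round(x$totals, 1))
  cat("cohort mean of per-patient means:\n")
  print(round(x$cohort_mean, 1))
  invisible(x)
}

#' Percent reduction of a penalty score vs the IGRT score
#'
#' `100 (1 - s_adapt / s_igrt)`, rounded to one decimal for reporting;
#' undefined (NA) when the IGRT score is zero.
#'
#' @param s_adapt penalty score of an adaptation approach.
#' @param s_igrt penalty score of the IGRT approach.
#' @return percent reduction (one decimal), or NA.
#' @export
percent_reduction <- function(s_adapt, s_igrt) {
  if (s_igrt == 0) return(NA_real_)
  round(100 * (1 - s_adapt / s_igrt), 1)
}
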