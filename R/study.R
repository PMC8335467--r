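#' Evaluate every approach on one fraction anatomy
#'
#' Builds the IGRT/ART1/ART2/ART3 dose distributions on the daily anatomy
#' (reusing the patient-level reference dose and distance maps from `cache`)
#' and evaluates each against the criterion table at course level.
#'
#' @param planning,daily [structure_set()]s.
#' @param registration the fraction `rigid_registration`.
#' @param params [dose_model_params()].
#' @param criteria criterion table.
#' @param seed per-fraction plan seed.
#' @param approaches subset of [approach_kinds()] (without REFERENCE).
#' @param patient,fraction labels.
#' @param cache patient-level environment (see [make_plan()]).
#' @param on_dose optional callback `function(approach, dose, structures)`
#'   invoked for each plan (used for DVH accumulation).
#' @return list of `plan_evaluation` objects, one per approach.
#' @export
evaluate_fraction <- function(planning, daily, registration,
                              params = dose_model_params(),
                              criteria = pace_criteria(), seed = 1,
                              approaches = c("IGRT", "ART1", "ART2", "ART3"),
                              patient = "P1", fraction = 1L,
                              cache = NULL, on_dose = NULL) {
  cache <- cache %||% new.env(parent = emptyenv())
  cache$daily_dist <- NULL  # distances to the daily PTV are per fraction
  out <- vector("list", length(approaches))
  names(out) <- approaches
  for (a in approaches) {
    dose <- make_plan(a, planning, daily, registration, params, seed, cache)
    if (!is.null(on_dose)) on_dose(a, dose, daily)
    out[[a]] <- evaluate_plan(dose, daily, criteria, patient, fraction, a)
  }
  out
}

new_dvh_accumulator <- function(structures = c("ctv", "ptv", "bladder", "rectum"),
                                bin_width = 0.25, max_dose = 50) {
  env <- new.env(parent = emptyenv())
  env$structures <- structures
  env$bin_width <- bin_width
  env$max_dose <- max_dose
  env$acc <- list()
  env$add <- function(approach, dose, ss) {
    for (st in structures) {
      cv <- cumulative_dvh(dose, ss$masks[[st]], bin_width, max_dose)
      key <- paste(approach, st, sep = ".")
      a <- env$acc[[key]]
      if (is.null(a)) a <- list(n = 0, s = 0, s2 = 0,
                                edges = cv$dose_edges)
      k <- length(a$edges)
      p <- cv$volume_pct[seq_len(k)]
      env$acc[[key]] <- list(n = a$n + 1, s = a$s + p, s2 = a$s2 + p^2,
                             edges = a$edges)
    }
  }
  env$as_df <- function() {
    do.call(rbind, lapply(names(env$acc), function(key) {
      a <- env$acc[[key]]
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      m <- a$s / a$n
      v <- pmax(0, (a$s2 - a$n * m^2) / (a$n - 1))
      data.frame(approach = parts[1], structure = parts[2],
                 dose_gy = a$edges, mean_pct = m,
                 sd_pct = if (a$n > 1) sqrt(v) else 0)
    }))
  }
  env
}

#' Run the full synthetic adaptation study
#'
#' Generates the cohort (default 32 patients x 5 fractions), builds the
#' reference plan per patient and the four adaptation plans per fraction
#' (640 adaptation plans + 32 reference plans at defaults), evaluates all
#' plans against the criterion table, and aggregates the penalty table,
#' paired t-tests, overlap-penalty correlations, trigger reports and mean
#' +/- SD DVH curves.
#'
#' Everything is a pure function of `(master_seed, cohort, dose)`; when
#' `out_dir` is given, canonical CSV/JSON outputs plus a run manifest are
#' written there.
#'
#' @param n_patients,n_fractions cohort size (defaults 32 x 5).
#' @param master_seed integer master seed.
#' @param cohort [cohort_params()].
#' @param dose [dose_model_params()].
#' @param criteria criterion table.
#' @param out_dir output directory, or `NULL` for in-memory results only.
#' @param dvh accumulate mean/SD DVH curves (slightly slower).
#' @param quiet suppress the per-fraction progress lines.
#' @return (invisibly when writing) list of class `study_result`:
#'   `evaluations` (tidy data.frame), `reference` (per-patient reference
#'   evaluations), `penalty_table`, `reductions`, `t_tests`,
#'   `correlations`, `triggers`, `dvh` (data.frame or NULL), `manifest`.
#' @export
run_study <- function(n_patients = 32, n_fractions = 5, master_seed = 1,
                      cohort = cohort_params(), dose = dose_model_params(),
                      criteria = pace_criteria(), out_dir = NULL,
                      dvh = TRUE, quiet = FALSE) {
  approaches <- c("IGRT", "ART1", "ART2", "ART3")
  acc <- if (dvh) new_dvh_accumulator()
  evals <- list()
  ref_evals <- list()

  for (i in seq_len(n_patients)) {
    pid <- sprintf("P%02d", i)
    tpl <- generate_patient(derive_seed(master_seed, i, 0), cohort,
                            patient_id = pid)
    grid <- default_grid(tpl, cohort)
    planning <- realize_structures(tpl, NULL, grid, cohort)
    cache <- new.env(parent = emptyenv())
    ident <- structure(list(translation = c(0, 0, 0), rotation = c(0, 0, 0)),
                       class = "rigid_registration")
    ref_dose <- make_plan("REFERENCE", planning, planning, ident, dose,
                          seed = derive_seed(master_seed, 5000 + i, 0), cache)
    if (dvh) acc$add("REFERENCE", ref_dose, planning)
    ref_evals[[pid]] <- evaluate_plan(ref_dose, planning, criteria,
                                      pid, 0L, "REFERENCE")
    for (j in seq_len(n_fractions)) {
      sc <- generate_scenario(tpl, j, derive_seed(master_seed, i, j), cohort)
      daily <- realize_structures(tpl, sc, grid, cohort)
      reg <- rigid_register(planning$masks$ctv, daily$masks$ctv, grid)
      fx <- evaluate_fraction(planning, daily, reg, dose, criteria,
                              seed = derive_seed(master_seed, 5000 + i, j),
                              approaches = approaches, patient = pid,
                              fraction = j, cache = cache,
                              on_dose = if (dvh) acc$add)
      evals <- c(evals, fx)
      if (!quiet)
        message(sprintf("%s fx%d  S: %s", pid, j,
                        paste(sprintf("%s=%.1f", approaches,
                                      vapply(fx, `[[`, 0, "S")),
                              collapse = " ")))
    }
  }

  eval_df <- evaluations_to_df(evals)
  ref_df <- evaluations_to_df(ref_evals)
  ptab <- cohort_penalty_table(eval_df)
  reductions <- list(
    total = sapply(c("ART1", "ART2", "ART3"), function(a)
      percent_reduction(ptab$totals[[a]], ptab$totals[["IGRT"]])),
    per_criterion = apply(ptab$per_criterion, 1, function(row)
      sapply(c("ART1", "ART2", "ART3"), function(a)
        percent_reduction(row[[a]], row[["IGRT"]]))))

  plans <- unique(eval_df[c("patient", "fraction", "approach", "S")])
  t_tests <- study_t_tests(eval_df, approaches)
  correlations <- study_correlations(plans, eval_df, approaches)
  triggers <- lapply(setNames(approaches, approaches), function(a)
    trigger_analysis(eval_df[eval_df$approach == a, ]))

  manifest <- list(
    tool = "adaptrt", version = as.character(utils::packageVersion("adaptrt")),
    master_seed = master_seed, n_patients = n_patients,
    n_fractions = n_fractions, approaches = approaches,
    n_adaptation_plans = n_patients * n_fractions * length(approaches),
    cohort_params = unclass(cohort), dose_params = unclass(dose),
    timestamp = format(Sys.time(), tz = "UTC"))

  res <- structure(list(evaluations = eval_df, reference = ref_df,
                        penalty_table = ptab, reductions = reductions,
                        t_tests = t_tests, correlations = correlations,
                        triggers = triggers,
                        dvh = if (dvh) acc$as_df(),
                        manifest = manifest),
                   class = "study_result")
  if (!is.null(out_dir)) {
    write_study(res, out_dir)
    return(invisible(res))
  }
  res
}

study_t_tests <- function(eval_df, approaches) {
  ids <- penalty_criterion_ids()
  pairs <- utils::combn(approaches, 2, simplify = FALSE)
  do.call(rbind, lapply(pairs, function(pr) {
    do.call(rbind, lapply(ids, function(id) {
      a <- eval_df[eval_df$id == id & eval_df$approach == pr[1], ]
      b <- eval_df[eval_df$id == id & eval_df$approach == pr[2], ]
      key <- paste(a$patient, a$fraction)
      b <- b[match(key, paste(b$patient, b$fraction)), ]
      tt <- paired_t_test(a$measured, b$measured)
      data.frame(comparison = paste(pr, collapse = " vs "), metric = id,
                 t = tt$t, p = tt$p, df = tt$df, mean_diff = tt$mean_diff)
    }))
  }))
}

study_correlations <- function(plans, eval_df, approaches) {
  ov <- unique(eval_df[c("patient", "fraction", "approach",
                         "overlap_bladder_cc", "overlap_rectum_cc")])
  do.call(rbind, lapply(approaches, function(a) {
    p <- plans[plans$approach == a, ]
    o <- ov[ov$approach == a, ]
    o <- o[match(paste(p$patient, p$fraction),
                 paste(o$patient, o$fraction)), ]
    # degenerate cohorts (constant S) get NA rather than an error
    safe_r <- function(x, y) tryCatch(pearson_r(x, y),
                                      error = function(e) NA_real_)
    data.frame(approach = a,
               organ = c("bladder", "rectum"),
               r = c(safe_r(o$overlap_bladder_cc, p$S),
                     safe_r(o$overlap_rectum_cc, p$S)),
               n = nrow(p))
  }))
}

write_study <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name)
    write.csv(df, file.path(out_dir, name), row.names = FALSE)
  wcsv(res$evaluations, "evaluations.csv")
  wcsv(res$reference, "reference_evaluations.csv")
  pt <- res$penalty_table
  wcsv(data.frame(criterion = rownames(pt$per_criterion),
                  pt$per_criterion, check.names = FALSE),
       "penalty_per_criterion.csv")
  wcsv(data.frame(patient = rownames(pt$per_patient_mean),
                  mean = pt$per_patient_mean, sd = pt$per_patient_sd,
                  check.names = FALSE),
       "penalty_per_patient.csv")
  wcsv(res$t_tests, "t_tests.csv")
  wcsv(res$correlations, "correlations.csv")
  if (!is.null(res$dvh)) wcsv(res$dvh, "dvh_mean_sd.csv")
  jsonlite::write_json(res$reductions,
                       file.path(out_dir, "reductions.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(lapply(res$triggers, function(tr)
                         lapply(tr, unclass)),
                       file.path(out_dir, "triggers.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d adaptation plans, totals: %s\n",
              x$manifest$n_adaptation_plans,
              paste(sprintf("%s=%.0f", names(x$penalty_table$totals),
                            x$penalty_table$totals), collapse = " ")))
  cat(" reductions vs IGRT:",
      paste(sprintf("%s=%.1f%%", names(x$reductions$total),
                    x$reductions$total), collapse = " "), "\n")
  invisible(x)
}
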