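#' Load the printed penalty-score table fixture
#'
#' The shipped fixture transcribes the published cohort penalty table: the
#' per-criterion sums over all 160 plans per approach, the per-patient
#' mean +/- SD over the 5 fraction plans, the printed column totals and the
#' printed cohort means. It is the input for the exact acceptance
#' arithmetic; the package never claims to reproduce the underlying patient
#' data.
#'
#' @param file optional alternative CSV path.
#' @return data.frame with columns panel, row, one value column per
#'   approach and matching `sd_*` columns.
#' @export
table3_printed <- function(file = NULL) {
  file <- file %||% system.file("extdata", "table3_printed.csv",
                                package = "adaptrt", mustWork = TRUE)
  tab <- read.csv(file, stringsAsFactors = FALSE)
  needed <- c("panel", "row", "reference", "igrt", "art1", "art2", "art3")
  miss <- setdiff(needed, names(tab))
  if (length(miss))
    stop("malformed fixture ", file, ": missing column(s) ",
         paste(miss, collapse = ", "))
  for (p in c("per_criterion", "total", "per_patient", "cohort_mean"))
    if (!any(tab$panel == p))
      stop("malformed fixture: panel '", p, "' absent")
  tab
}

#' Verify the printed penalty-table arithmetic
#'
#' Recomputes, from the fixture's raw per-criterion and per-patient entries:
#' the column totals, the cohort means of the per-patient means, the total
#' penalty reductions of each adaptation approach vs IGRT, the per-criterion
#' reductions, and the PTV/OAR criterion-averaged reductions. Each recomputed
#' quantity is compared against the value printed in the fixture itself and
#' mismatches are flagged.
#'
#' @param fixture a [table3_printed()] data.frame or a path to one.
#' @param tol absolute tolerance for the printed (rounded) values.
#' @return list of class `table3_report`: `totals`, `printed_totals`,
#'   `cohort_means`, `printed_means`, `reductions` (per approach),
#'   `criterion_reductions` (criterion x approach), `ptv_avg_reduction`,
#'   `oar_avg_reduction`, `mismatches` (character vector, empty when all
#'   printed values are consistent).
#' @export
verify_printed_table <- function(fixture = table3_printed(), tol = 0.051) {
  tab <- if (is.character(fixture)) table3_printed(fixture) else fixture
  ap <- c("reference", "igrt", "art1", "art2", "art3")
  adapt <- c("art1", "art2", "art3")

  crit <- tab[tab$panel == "per_criterion", ]
  if (nrow(crit) != 4) stop("malformed fixture: expected 4 criterion rows")
  totals <- colSums(crit[ap])
  printed_totals <- unlist(tab[tab$panel == "total", ap])

  pat <- tab[tab$panel == "per_patient", ]
  cohort_means <- round(colMeans(pat[ap]), 1)
  printed_means <- unlist(tab[tab$panel == "cohort_mean", ap])

  reductions <- vapply(adapt, function(a)
    percent_reduction(totals[[a]], totals[["igrt"]]), numeric(1))
  criterion_reductions <- sapply(adapt, function(a)
    vapply(seq_len(nrow(crit)), function(i)
      percent_reduction(crit[[a]][i], crit[["igrt"]][i]), numeric(1)))
  rownames(criterion_reductions) <- crit$row

  ptv_rows <- crit$row %in% c("V36.25Gy_PTV", "D98pct_PTV")
  raw_red <- function(a, rows)
    100 * (1 - crit[[a]][rows] / crit[["igrt"]][rows])
  ptv_avg <- vapply(adapt, function(a)
    round(mean(raw_red(a, ptv_rows)), 1), numeric(1))
  oar_avg <- vapply(adapt, function(a)
    round(mean(raw_red(a, !ptv_rows)), 1), numeric(1))

  mism <- character(0)
  for (a in ap) {
    if (abs(totals[[a]] - printed_totals[[a]]) > tol)
      mism <- c(mism, sprintf(
        "total[%s]: recomputed %.1f vs printed %.1f", a,
        totals[[a]], printed_totals[[a]]))
    if (abs(cohort_means[[a]] - printed_means[[a]]) > tol)
      mism <- c(mism, sprintf(
        "cohort_mean[%s]: recomputed %.1f vs printed %.1f", a,
        cohort_means[[a]], printed_means[[a]]))
  }

  structure(list(totals = totals, printed_totals = printed_totals,
                 cohort_means = cohort_means, printed_means = printed_means,
                 reductions = reductions,
                 criterion_reductions = criterion_reductions,
                 ptv_avg_reduction = ptv_avg, oar_avg_reduction = oar_avg,
                 mismatches = mism),
            class = "table3_report")
}

#' @export
print.table3_report <- function(x, ...) {
  cat("<table3_report>\n totals:", paste(names(x$totals), x$totals,
                                         collapse = " "), "\n")
  cat(" reductions vs IGRT (%):",
      paste(names(x$reductions), x$reductions, collapse = " "), "\n")
  if (length(x$mismatches)) {
    cat(" MISMATCHES:\n")
    for (m in x$mismatches) cat("  -", m, "\n")
  } else cat(" printed totals and cohort means verified\n")
  invisible(x)
}
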