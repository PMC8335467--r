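#' Paired Student's t-test
#'
#' Classic paired t on the differences `x - y`, two-sided p from the t
#' distribution with n - 1 degrees of freedom. Zero-variance differences
#' (including `x == y`) are reported as p = 1 with a degenerate flag instead
#' of NaN.
#'
#' @param x,y paired numeric vectors of equal length >= 3.
#' @return list: `t`, `p`, `df`, `mean_diff`, `degenerate`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs")
  d <- x - y
  sdd <- sd(d)
  if (sdd == 0) {
    return(list(t = 0, p = 1, df = n - 1, mean_diff = mean(d),
                degenerate = TRUE))
  }
  t <- mean(d) / (sdd / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), df = n - 1), df = n - 1,
       mean_diff = mean(d), degenerate = FALSE)
}

#' Pearson correlation coefficient
#'
#' Sample Pearson correlation, computed from the sample covariance and
#' standard deviations.
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return r in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for a constant vector")
  r <- sum((x - mean(x)) * (y - mean(y))) /
       ((length(x) - 1) * sd(x) * sd(y))
  clamp(r, -1, 1)
}

#' Overlap-volume adaptation trigger analysis
#'
#' For one approach, a plan "overdoses" an organ when V37Gy(bladder) > 9 cc
#' or V36Gy(rectum) > 1.5 cc. The trigger ratio is the fraction of
#' overdosing plans whose PTV-organ overlap volume exceeds the cohort mean
#' overlap (overlaps are anatomy properties, pooled over all fraction
#' anatomies).
#'
#' @param eval_df tidy evaluation table ([evaluations_to_df()]) restricted
#'   to one approach.
#' @param mean_overlap optional named vector `c(bladder = , rectum = )` of
#'   the pooled mean overlaps; computed from `eval_df` when omitted.
#' @return list of two `trigger_report` lists (bladder, rectum) with fields
#'   `organ`, `rule`, `mean_overlap_cc`, `n_plans`, `n_overdose`,
#'   `n_joint`, `ratio` (NA when no plan overdoses).
#' @export
trigger_analysis <- function(eval_df, mean_overlap = NULL) {
  if (length(unique(eval_df$approach)) != 1)
    stop("trigger_analysis expects evaluations of a single approach")
  rules <- list(
    bladder = list(id = "V37Gy_bladder", thr = 9,
                   overlap_col = "overlap_bladder_cc",
                   rule = "V37Gy(bladder) > 9 cc"),
    rectum = list(id = "V36Gy_rectum", thr = 1.5,
                  overlap_col = "overlap_rectum_cc",
                  rule = "V36Gy(rectum) > 1.5 cc"))
  out <- lapply(names(rules), function(organ) {
    ru <- rules[[organ]]
    rows <- eval_df[eval_df$id == ru$id, ]
    if (!nrow(rows)) stop("criterion ", ru$id, " missing from evaluations")
    mo <- if (!is.null(mean_overlap)) mean_overlap[[organ]]
          else mean(rows[[ru$overlap_col]])
    over <- rows$measured > ru$thr
    joint <- over & rows[[ru$overlap_col]] > mo
    structure(list(
      organ = organ,
      rule = ru$rule,
      mean_overlap_cc = mo,
      n_plans = nrow(rows),
      n_overdose = sum(over),
      n_joint = sum(joint),
      ratio = if (sum(over) > 0) sum(joint) / sum(over) else NA_real_),
      class = "trigger_report")
  })
  names(out) <- names(rules)
  out
}
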