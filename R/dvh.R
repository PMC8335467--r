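mask_doses <- function(dose, mask) {
  if (inherits(dose, "dose_grid")) {
    if (!all(dim(mask) == dose$grid$dim))
      stop("mask does not match the dose lattice")
    dose$values[mask]
  } else dose[mask]
}

#' Cumulative dose-volume histogram
#'
#' Bin `b` stores the volume of structure voxels receiving at least
#' `dose_edges[b]`; volume is the exact voxel count times the voxel volume.
#' The binned curve exists for plotting and point-wise statistics; scalar
#' metrics ([v_dose()], [d_volume()]) are computed voxel-exactly instead.
#'
#' @param dose a [dose_grid()].
#' @param mask logical structure mask (non-empty).
#' @param bin_width Gy (default 0.05).
#' @param max_dose top of the dose axis; default 1.25 x 40 Gy = 50 Gy
#'   (extended if the structure sees more).
#' @return object of class `dvh_curve` with `dose_edges`, `volume_cc`,
#'   `volume_pct` and `structure_volume_cc`.
#' @export
cumulative_dvh <- function(dose, mask, bin_width = 0.05, max_dose = 50) {
  if (!any(mask)) stop("cannot compute a DVH of an empty structure")
  if (bin_width <= 0) stop("bin width must be positive")
  dv <- mask_doses(dose, mask)
  vv <- voxel_volume_cc(dose$grid)
  top <- max(max_dose, max(dv) + bin_width)
  edges <- seq(0, top, by = bin_width)
  # volume with dose >= edge: reverse cumulative histogram
  counts <- rev(cumsum(rev(tabulate(
    findInterval(dv, edges, left.open = FALSE), nbins = length(edges)))))
  vol_cc <- counts * vv
  structure(list(dose_edges = edges, volume_cc = vol_cc,
                 volume_pct = 100 * counts / length(dv),
                 structure_volume_cc = length(dv) * vv),
            class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("<dvh_curve> structure %.2f cc, %d bins of %.3g Gy\n",
              x$structure_volume_cc, length(x$dose_edges),
              x$dose_edges[2] - x$dose_edges[1]))
  invisible(x)
}

#' V_xGy: structure volume receiving at least a dose threshold
#'
#' Computed voxel-exactly (count of mask voxels with dose >= threshold times
#' the voxel volume), not from a binned curve.
#'
#' @param dose a [dose_grid()].
#' @param mask logical structure mask (non-empty).
#' @param threshold Gy, >= 0.
#' @param mode `"relative"` (% of structure volume) or `"absolute"` (cc).
#' @return scalar volume.
#' @export
v_dose <- function(dose, mask, threshold, mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  if (threshold < 0) stop("threshold must be non-negative")
  if (!any(mask)) stop("empty structure")
  dv <- mask_doses(dose, mask)
  n <- sum(dv >= threshold)
  if (mode == "relative") 100 * n / length(dv)
  else n * voxel_volume_cc(dose$grid)
}

#' D_x%: minimum dose to the hottest x% of a structure
#'
#' The largest dose `d` such that at least `p`% of the structure receives at
#' least `d`, i.e. the `(100 - p)`% quantile of the voxel doses, with linear
#' interpolation between adjacent order statistics.
#'
#' @param dose a [dose_grid()].
#' @param mask logical structure mask (non-empty).
#' @param volume_pct percent in (0, 100].
#' @return dose in Gy.
#' @export
d_volume <- function(dose, mask, volume_pct) {
  if (volume_pct <= 0 || volume_pct > 100)
    stop("volume_pct must lie in (0, 100]")
  if (!any(mask)) stop("empty structure")
  dv <- sort(mask_doses(dose, mask))
  n <- length(dv)
  if (n == 1) return(dv)
  h <- (n - 1) * (1 - volume_pct / 100) + 1
  lo <- floor(h)
  dv[lo] + (h - lo) * (dv[min(lo + 1, n)] - dv[lo])
}

#' Overlap volume of two masks
#'
#' @param a,b logical masks on the same lattice.
#' @param grid the shared `grid_spec`.
#' @return volume of the intersection in cc.
#' @export
overlap_volume <- function(a, b, grid) {
  if (!all(dim(a) == dim(b)) || !all(dim(a) == grid$dim))
    stop("masks must share the grid lattice")
  sum(a & b) * voxel_volume_cc(grid)
}

#' Point-wise mean and SD across DVH curves
#'
#' Per-bin arithmetic mean and sample SD (n - 1) of the relative-volume
#' curves; all curves must share one dose axis.
#'
#' @param curves list of >= 2 [cumulative_dvh()] results.
#' @return list with `dose_edges`, `mean_pct`, `sd_pct`, `n`.
#' @export
pointwise_dvh_stats <- function(curves) {
  if (length(curves) < 2) stop("need at least two curves")
  edges <- curves[[1]]$dose_edges
  for (cv in curves)
    if (length(cv$dose_edges) != length(edges) ||
        any(abs(cv$dose_edges - edges) > 1e-9))
      stop("curves must share an identical dose axis")
  m <- vapply(curves, function(cv) cv$volume_pct, numeric(length(edges)))
  list(dose_edges = edges,
       mean_pct = rowMeans(m),
       sd_pct = apply(m, 1, sd),
       n = length(curves))
}
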