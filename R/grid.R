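#' Regular voxel lattice specification
#'
#' A lattice is shared between dose grids and structure sets: physical
#' coordinates are `origin + index * spacing` (0-based indices), axes ordered
#' (L-R, A-P, I-S), all in mm.
#'
#' @param spacing numeric(3), voxel spacing in mm (all > 0).
#' @param origin numeric(3), physical coordinate of voxel (0,0,0) in mm.
#' @param dim integer(3), number of voxels along each axis.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(spacing, origin, dim) {
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  dim <- as.integer(dim)
  stopifnot(length(spacing) == 3, length(origin) == 3, length(dim) == 3)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("grid spacing must be positive and finite")
  if (any(dim < 1)) stop("grid dim must be >= 1")
  structure(list(spacing = spacing, origin = origin, dim = dim),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d x %d voxels, spacing %s mm, origin %s mm\n",
              x$dim[1], x$dim[2], x$dim[3],
              paste(format(x$spacing), collapse = " x "),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

#' Voxel-centre coordinates along each axis
#' @param grid a `grid_spec`.
#' @return list with numeric vectors `x`, `y`, `z` (mm).
#' @export
grid_coords <- function(grid) {
  list(x = grid$origin[1] + (seq_len(grid$dim[1]) - 1) * grid$spacing[1],
       y = grid$origin[2] + (seq_len(grid$dim[2]) - 1) * grid$spacing[2],
       z = grid$origin[3] + (seq_len(grid$dim[3]) - 1) * grid$spacing[3])
}

#' Voxel volume in cc
#' @param grid a `grid_spec`.
#' @return scalar, cm^3 per voxel (1 voxel at 2 mm iso = 0.008 cc).
#' @export
voxel_volume_cc <- function(grid) prod(grid$spacing) / 1000

same_lattice <- function(a, b, tol = 1e-9) {
  all(a$dim == b$dim) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Dose grid container
#'
#' @param values 3D numeric array of dose in Gy; must be finite and >= 0.
#' @param grid the `grid_spec` the values live on.
#' @return object of class `dose_grid` with elements `values` and `grid`.
#' @export
dose_grid <- function(values, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!is.array(values) || !all(dim(values) == grid$dim))
    stop("dose values must be a 3D array matching grid dim")
  if (any(!is.finite(values)) || any(values < 0))
    stop("dose values must be finite and non-negative")
  structure(list(values = values, grid = grid), class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> max %.2f Gy on %d x %d x %d lattice\n",
              max(x$values), x$grid$dim[1], x$grid$dim[2], x$grid$dim[3]))
  invisible(x)
}

#' Structure set container
#'
#' Named binary organ masks sharing one lattice. The CTV/PTV nesting and
#' non-empty volumes of the four scored structures are enforced when present.
#'
#' @param masks named list of logical 3D arrays.
#' @param grid shared `grid_spec`.
#' @param provenance `"planning"` or `"fraction <k>"`.
#' @return object of class `structure_set`.
#' @export
structure_set <- function(masks, grid, provenance = "planning") {
  stopifnot(inherits(grid, "grid_spec"), is.list(masks), length(masks) > 0)
  if (is.null(names(masks)) || any(names(masks) == ""))
    stop("all masks must be named")
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!is.logical(m) || !all(dim(m) == grid$dim))
      stop("mask '", nm, "' must be a logical array matching grid dim")
  }
  for (nm in intersect(c("ctv", "ptv", "bladder", "rectum"), names(masks)))
    if (!any(masks[[nm]])) stop("mask '", nm, "' is empty")
  if (all(c("ctv", "ptv") %in% names(masks)) &&
      any(masks$ctv & !masks$ptv))
    stop("CTV must be contained in PTV")
  structure(list(masks = masks, grid = grid, provenance = provenance),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  vv <- voxel_volume_cc(x$grid)
  vols <- vapply(x$masks, function(m) sum(m) * vv, numeric(1))
  cat(sprintf("<structure_set> (%s) %s\n", x$provenance,
              paste(sprintf("%s=%.1fcc", names(vols), vols), collapse = " ")))
  invisible(x)
}

#' Mask centroid in physical coordinates
#' @param mask logical 3D array.
#' @param grid `grid_spec`.
#' @return numeric(3), mm.
#' @export
mask_centroid <- function(mask, grid) {
  if (!any(mask)) stop("cannot take the centroid of an empty mask")
  idx <- which(mask, arr.ind = TRUE)
  unname((colMeans(idx) - 1) * grid$spacing + grid$origin)
}

#' Euclidean distance map to a mask
#'
#' Exact Euclidean distance (mm) from each voxel centre to the set of mask
#' voxel centres; 0 inside the mask.
#' @param mask logical 3D array.
#' @param grid `grid_spec`.
#' @return numeric 3D array of distances in mm.
#' @export
distance_to_mask <- function(mask, grid) {
  if (!any(mask)) stop("distance map of an empty mask is undefined")
  array(.edt3d(as.logical(mask), grid$dim, grid$spacing), dim = grid$dim)
}
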