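#' Parameters of the parametric dose engine
#'
#' The engine replaces a treatment planning system with an explicit
#' distance-based archetype: a uniform plateau over the PTV falling off as a
#' Gaussian penumbra outside it, modulated by a smooth multiplicative noise
#' field. Approach differences are encoded entirely in these parameters:
#'
#' * `penumbra_sigma` (mm): Gaussian falloff scale per approach; the
#'   reference/IGRT and ART1 plans share the widest penumbra, ART2 is
#'   sharper, ART3 sharpest.
#' * `conformity` (mm): distance offset before the falloff starts, i.e. how
#'   far the prescription plateau leaks beyond the PTV; degrades from the
#'   reference plans down to 0 for the fully re-optimized ART3.
#' * `oar_sparing_depth` / `oar_interface_margin`: ART3-only dose carving
#'   inside organs at risk beyond an interface shell around the PTV.
#' * `noise_amplitude` / `noise_correlation_length`: lognormal multiplicative
#'   noise of the stated relative amplitude (default 2%, emulating Monte
#'   Carlo statistical noise) and correlation length (mm).
#'
#' The PTV-interior plateau equals `prescription_ctv` (40 Gy): the PTV
#' prescription 36.25 Gy times an interior boost of
#' `prescription_ctv / prescription_ptv`.
#'
#' @param ... overrides for any default element.
#' @return list of class `dose_model_params`.
#' @export
dose_model_params <- function(...) {
  p <- list(
    prescription_ctv = 40,
    prescription_ptv = 36.25,
    target_coverage_pct = 95,
    penumbra_sigma = c(REFERENCE = 4, IGRT = 4, ART1 = 4, ART2 = 3.5, ART3 = 3),
    conformity     = c(REFERENCE = 2, IGRT = 2, ART1 = 1, ART2 = 0.5, ART3 = 0),
    oar_sparing_depth = 0.3,
    oar_interface_margin = 3,
    noise_amplitude = 0.02,
    noise_correlation_length = 5
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop("unknown dose model parameter(s): ",
                        paste(bad, collapse = ", "))
  p[names(ov)] <- ov
  s <- p$penumbra_sigma
  if (any(s <= 0)) stop("penumbra sigma must be positive")
  if (!(abs(s["IGRT"] - s["REFERENCE"]) < 1e-12 &&
        abs(s["ART1"] - s["REFERENCE"]) < 1e-12 &&
        s["ART1"] >= s["ART2"] && s["ART2"] >= s["ART3"]))
    stop("penumbra sigma must satisfy REFERENCE = IGRT = ART1 >= ART2 >= ART3")
  if (p$oar_sparing_depth < 0 || p$oar_sparing_depth > 1)
    stop("oar_sparing_depth must lie in [0, 1]")
  if (p$noise_amplitude < 0 || p$noise_correlation_length <= 0)
    stop("invalid noise parameters")
  class(p) <- "dose_model_params"
  p
}

#' Treatment planning approaches
#'
#' `REFERENCE` is the plan optimized on the planning anatomy; `IGRT` copies
#' it unaltered onto the registered daily anatomy; `ART1`/`ART2` re-conform
#' to the daily PTV with decreasing penumbra degradation and are rescaled to
#' CTV coverage; `ART3` is a full re-optimization with additional OAR
#' sparing, also rescaled.
#' @return character vector of the five approach labels.
#' @export
approach_kinds <- function() c("REFERENCE", "IGRT", "ART1", "ART2", "ART3")

#' Smooth multiplicative noise field
#'
#' Gaussian white noise smoothed with an isotropic kernel of the given
#' correlation length, standardized, then exponentiated as
#' `exp(a g - a^2/2)` so the field is positive with mean ~1 and relative
#' amplitude `a`.
#' @param grid a `grid_spec`.
#' @param amplitude relative amplitude (0 disables).
#' @param correlation_length mm.
#' @param seed integer seed.
#' @return numeric 3D array.
#' @export
noise_field <- function(grid, amplitude, correlation_length, seed) {
  if (amplitude == 0) return(array(1, grid$dim))
  set.seed(as.integer(seed))
  g <- rnorm(prod(grid$dim))
  g <- .gauss3d(g, grid$dim, grid$spacing, correlation_length)
  g <- (g - mean(g)) / sd(g)
  array(exp(amplitude * g - amplitude^2 / 2), grid$dim)
}

#' Conformal dose archetype for one PTV
#'
#' `D(x) = P exp(-d'(x)^2 / (2 sigma^2))` with `d'` the Euclidean distance to
#' the PTV reduced by the approach's conformity offset (0 inside the PTV) and
#' `P` the CTV prescription plateau, times the multiplicative noise field.
#'
#' @param ptv logical PTV mask.
#' @param grid `grid_spec`.
#' @param params [dose_model_params()].
#' @param approach one of [approach_kinds()].
#' @param noise_seed integer.
#' @param dist optional precomputed [distance_to_mask()] for `ptv`.
#' @return a [dose_grid()].
#' @export
conformal_dose <- function(ptv, grid, params = dose_model_params(),
                           approach = "REFERENCE", noise_seed = 1,
                           dist = NULL) {
  approach <- match.arg(approach, approach_kinds())
  if (!any(ptv)) stop("cannot plan on an empty PTV")
  d <- dist %||% distance_to_mask(ptv, grid)
  deff <- pmax(d - params$conformity[[approach]], 0)
  plateau <- params$prescription_ptv *
    (params$prescription_ctv / params$prescription_ptv)  # interior boost
  sig <- params$penumbra_sigma[[approach]]
  values <- plateau * exp(-deff^2 / (2 * sig^2))
  values <- values * noise_field(grid, params$noise_amplitude,
                                 params$noise_correlation_length, noise_seed)
  dose_grid(array(values, grid$dim), grid)
}

#' OAR interface sparing (ART3 archetype)
#'
#' Inside each OAR, beyond an interface shell of width `m =
#' oar_interface_margin` around the PTV, the dose is multiplied by
#' `1 - depth * w(x)` with `w = clamp((d - m)/m, 0, 1)`: untouched within the
#' shell, full sparing from distance `2 m` outward. Voxels outside the OARs
#' are unchanged bit-exactly.
#'
#' @param dose a [dose_grid()].
#' @param oars list of logical OAR masks.
#' @param ptv logical PTV mask.
#' @param params [dose_model_params()].
#' @param dist optional precomputed distance map to the PTV.
#' @return a [dose_grid()].
#' @export
oar_spare <- function(dose, oars, ptv, params = dose_model_params(),
                      dist = NULL) {
  grid <- dose$grid
  if (params$oar_sparing_depth == 0) return(dose)
  d <- dist %||% distance_to_mask(ptv, grid)
  m <- params$oar_interface_margin
  oar_any <- Reduce(`|`, oars)
  w <- clamp((d[oar_any] - m) / m, 0, 1)
  values <- dose$values
  values[oar_any] <- values[oar_any] * (1 - params$oar_sparing_depth * w)
  dose_grid(values, grid)
}

#' Resample a dose grid under a rigid registration
#'
#' `output(x) = input(T^-1 x)` with `T` the translation followed by the
#' rotation about `centre` (the planning CTV centroid) when rotations are
#' present; trilinear interpolation, 0 Gy outside the source grid.
#'
#' @param reference_dose a [dose_grid()].
#' @param registration a `rigid_registration`.
#' @param centre rotation centre (mm); defaults to the grid centre.
#' @return a [dose_grid()] on the same lattice.
#' @export
transform_dose <- function(reference_dose, registration, centre = NULL) {
  grid <- reference_dose$grid
  if (any(!is.finite(registration$translation)) ||
      any(!is.finite(registration$rotation)))
    stop("registration must be finite")
  centre <- centre %||% (grid$origin + (grid$dim - 1) / 2 * grid$spacing)
  rot <- euler_matrix(registration$rotation)
  out <- .resample_rigid(as.numeric(reference_dose$values), grid$dim,
                         grid$spacing, grid$origin,
                         as.numeric(registration$translation),
                         as.numeric(t(rot)), as.numeric(centre))
  dose_grid(array(pmax(out, 0), grid$dim), grid)
}

euler_matrix <- function(deg) {
  r <- deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  Rz %*% Ry %*% Rx
}

#' Rescale a plan to a CTV coverage prescription
#'
#' Multiplies the dose by `target_dose / D_p%(CTV)` so that the recomputed
#' `D_p%(CTV)` equals the target to floating precision (PACE-C: 40 Gy to 95%
#' of the CTV).
#'
#' @param dose a [dose_grid()].
#' @param ctv logical CTV mask.
#' @param target_dose Gy (default 40).
#' @param target_volume_pct percent (default 95).
#' @return rescaled [dose_grid()].
#' @export
rescale_to_coverage <- function(dose, ctv, target_dose = 40,
                                target_volume_pct = 95) {
  if (!any(ctv)) stop("cannot rescale on an empty CTV")
  dcur <- d_volume(dose, ctv, target_volume_pct)
  if (dcur <= 0) stop("input dose is zero over the CTV; cannot rescale")
  dose_grid(dose$values * (target_dose / dcur), dose$grid)
}

#' Build the dose distribution of one approach on one daily anatomy
#'
#' * `REFERENCE`: conformal dose on the planning PTV, no rescale.
#' * `IGRT`: the reference dose copied unaltered onto the registered daily
#'   anatomy ([transform_dose()]), no rescale.
#' * `ART1`/`ART2`: conformal dose on the daily PTV with approach-specific
#'   penumbra/conformity, rescaled to `D_95%(CTV) = 40 Gy`.
#' * `ART3`: as ART2 but with the sharpest parameters plus [oar_spare()],
#'   then rescaled.
#'
#' The reference noise seed is shared by REFERENCE and IGRT so that with an
#' identical daily anatomy the IGRT plan reproduces the reference plan.
#'
#' @param approach one of [approach_kinds()].
#' @param planning,daily [structure_set()]s on a shared lattice.
#' @param registration the fraction's `rigid_registration`.
#' @param params [dose_model_params()].
#' @param seed integer plan seed (per patient-fraction).
#' @param cache optional environment for reusing distance maps and the
#'   reference dose across approaches of the same fraction.
#' @return a [dose_grid()].
#' @export
make_plan <- function(approach, planning, daily, registration,
                      params = dose_model_params(), seed = 1, cache = NULL) {
  approach <- match.arg(approach, approach_kinds())
  grid <- planning$grid
  if (!same_lattice(grid, daily$grid))
    stop("planning and daily lattices must match")
  cache <- cache %||% new.env(parent = emptyenv())

  ref_dose <- function() {
    if (is.null(cache$reference)) {
      if (is.null(cache$planning_dist))
        cache$planning_dist <- distance_to_mask(planning$masks$ptv, grid)
      cache$reference <- conformal_dose(
        planning$masks$ptv, grid, params, "REFERENCE",
        noise_seed = derive_seed(seed, 1L), dist = cache$planning_dist)
    }
    cache$reference
  }
  daily_dist <- function() {
    if (is.null(cache$daily_dist))
      cache$daily_dist <- distance_to_mask(daily$masks$ptv, grid)
    cache$daily_dist
  }

  if (approach == "REFERENCE") return(ref_dose())
  if (approach == "IGRT") {
    centre <- mask_centroid(planning$masks$ctv, grid)
    return(transform_dose(ref_dose(), registration, centre = centre))
  }
  dose <- conformal_dose(daily$masks$ptv, grid, params, approach,
                         noise_seed = derive_seed(seed, match(approach, approach_kinds())),
                         dist = daily_dist())
  if (approach == "ART3")
    dose <- oar_spare(dose, daily$masks[c("bladder", "rectum")],
                      daily$masks$ptv, params, dist = daily_dist())
  rescale_to_coverage(dose, daily$masks$ctv,
                      params$prescription_ctv, params$target_coverage_pct)
}
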