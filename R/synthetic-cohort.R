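#' Cohort distribution settings
#'
#' Defaults describe a pelvic anatomy distribution whose voxelized prostate
#' volumes reproduce a 65.3 +/- 26.3 cc spread (lognormal), with bladder and
#' rectum placed so that planning-anatomy plans meet the scored constraints
#' while daily filling changes produce occasional violations.
#'
#' All lengths in mm, volumes in cc. `deform_sdlog` is the per-axis lognormal
#' sdlog of the daily prostate semi-axis scaling (A-P axis most variable,
#' emulating rectal-filling-driven target deformation of up to ~6 mm).
#'
#' @param ... overrides for any default element.
#' @return list of class `cohort_params`.
#' @export
cohort_params <- function(...) {
  p <- list(
    prostate_volume_meanlog = log(65.3) - 0.5 * log(1 + (26.3 / 65.3)^2),
    prostate_volume_sdlog  = sqrt(log(1 + (26.3 / 65.3)^2)),
    axis_ratio_base        = c(1.05, 0.95, 1.00),   # L-R, A-P, I-S
    axis_ratio_sdlog       = 0.05,
    sv_lateral_offset      = 11,     # lobe centres at +/- this (mm)
    sv_semiaxes            = c(8, 6, 14),
    sv_posterior_frac      = 0.6,    # lobe centre y = -frac * b
    bladder_radius_mean    = 35,
    bladder_radius_sd      = 4,
    bladder_gap_mean       = -6,     # bladder surface minus prostate surface
    bladder_gap_sd         = 2,      # (negative = bladder neck overlaps)
    bladder_angle_deg      = 25,     # anterior tilt of the bladder direction
    rectum_radius_mean     = 15,
    rectum_radius_sd       = 1.5,
    rectum_gap_mean        = 4.0,      # prostate surface to rectum surface
    rectum_gap_sd          = 0.8,
    rectum_half_length     = 50,
    margin_mm              = 4,      # CTV -> PTV
    shift_sd               = c(1.5, 3.5, 3),
    shift_cap              = 10,
    fill_sdlog_bladder     = 0.25,
    fill_sdlog_rectum      = 0.25,
    fill_bounds            = c(0.6, 1.6),
    deform_sdlog           = c(0.06, 0.08, 0.06),
    deform_bounds          = c(0.78, 1.3),
    deform                 = TRUE,
    grid_spacing           = c(2, 2, 2),
    grid_padding           = 20
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop("unknown cohort parameter(s): ", paste(bad, collapse = ", "))
  p[names(ov)] <- ov
  if (p$prostate_volume_sdlog <= 0 || p$bladder_radius_mean <= 0 ||
      p$rectum_radius_mean <= 0 || any(p$grid_spacing <= 0))
    stop("invalid cohort configuration: non-positive scale parameter")
  if (p$fill_bounds[1] <= 0 || diff(p$fill_bounds) < 0)
    stop("invalid fill bounds")
  class(p) <- "cohort_params"
  p
}

#' Draw one synthetic patient template
#'
#' The prostate is an ellipsoid (volume lognormal), the seminal vesicles two
#' posterior-superior lobes whose proximal 1 cm joins the CTV, the bladder a
#' sphere superior-anterior of the prostate and the rectum a capsule posterior
#' of it. Deterministic given `seed`.
#'
#' @param seed integer seed for this patient.
#' @param params a [cohort_params()] list.
#' @param patient_id label; defaults to `"P<seed>"`.
#' @return list of class `patient_template`.
#' @export
generate_patient <- function(seed, params = cohort_params(),
                             patient_id = sprintf("P%d", seed)) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(as.integer(seed))
  vol_cc <- exp(rnorm(1, params$prostate_volume_meanlog,
                      params$prostate_volume_sdlog))
  ratios <- params$axis_ratio_base * exp(rnorm(3, 0, params$axis_ratio_sdlog))
  # solve k so that (k r1)(k r2)(k r3) 4pi/3 = vol (mm^3)
  k <- (vol_cc * 1000 * 3 / (4 * pi * prod(ratios)))^(1 / 3)
  semiaxes <- k * ratios
  b <- semiaxes[2]; cz <- semiaxes[3]

  sv_zbase <- 0.5 * cz
  sv_centers <- list(
    c(-params$sv_lateral_offset, -params$sv_posterior_frac * b,
      sv_zbase + params$sv_semiaxes[3]),
    c(+params$sv_lateral_offset, -params$sv_posterior_frac * b,
      sv_zbase + params$sv_semiaxes[3]))

  ang <- params$bladder_angle_deg * pi / 180
  u <- c(0, sin(ang), cos(ang))
  r_u <- 1 / sqrt((u[2] / b)^2 + (u[3] / cz)^2)  # prostate radius along u
  bl_r <- max(20, rnorm(1, params$bladder_radius_mean, params$bladder_radius_sd))
  bl_gap <- rnorm(1, params$bladder_gap_mean, params$bladder_gap_sd)
  bladder_center <- u * (r_u + bl_gap + bl_r)

  re_r <- clamp(rnorm(1, params$rectum_radius_mean, params$rectum_radius_sd),
                11, 20)
  re_gap <- max(0.5, rnorm(1, params$rectum_gap_mean, params$rectum_gap_sd))
  re_x <- rnorm(1, 0, 1)
  re_y <- -(b + re_gap + re_r)
  rectum_axis <- rbind(c(re_x, re_y, -params$rectum_half_length),
                       c(re_x, re_y, +params$rectum_half_length))

  tpl <- structure(list(
    patient_id = patient_id,
    prostate_center = c(0, 0, 0),
    prostate_semiaxes = semiaxes,
    sv_centers = sv_centers,
    sv_semiaxes = params$sv_semiaxes,
    sv_ctv_zcut = sv_zbase + 10,   # proximal 1 cm of the SV joins the CTV
    bladder_center = bladder_center,
    bladder_base_radius = bl_r,
    rectum_axis = rectum_axis,
    rectum_base_radius = re_r,
    seed = as.integer(seed),
    params = params), class = "patient_template")
  validate_template(tpl)
  tpl
}

validate_template <- function(tpl) {
  if (any(tpl$prostate_semiaxes <= 0) || tpl$bladder_base_radius <= 0 ||
      tpl$rectum_base_radius <= 0 || any(tpl$sv_semiaxes <= 0))
    stop("template invariant violated: non-positive radius or semi-axis")
  if (!(tpl$bladder_center[2] > tpl$prostate_center[2] &&
        tpl$bladder_center[3] > tpl$prostate_center[3]))
    stop("template invariant violated: bladder must be superior-anterior")
  if (!(tpl$rectum_axis[1, 2] < tpl$prostate_center[2]))
    stop("template invariant violated: rectum must be posterior")
  invisible(tpl)
}

#' Per-fraction deformation scenario
#'
#' @param fraction_index integer >= 1.
#' @param prostate_shift numeric(3) mm.
#' @param bladder_fill_scale,rectum_fill_scale dimensionless volume scales.
#' @param deformation_seed integer driving the daily prostate-axis scaling.
#' @param params [cohort_params()]; supplies fill bounds and the shift cap.
#' @return list of class `fraction_scenario`.
#' @export
fraction_scenario <- function(fraction_index, prostate_shift,
                              bladder_fill_scale, rectum_fill_scale,
                              deformation_seed,
                              params = cohort_params()) {
  stopifnot(fraction_index >= 1)
  if (sqrt(sum(prostate_shift^2)) > params$shift_cap + 1e-9)
    stop("prostate shift exceeds the configured cap")
  fb <- params$fill_bounds
  if (bladder_fill_scale < fb[1] - 1e-9 || bladder_fill_scale > fb[2] + 1e-9 ||
      rectum_fill_scale < fb[1] - 1e-9 || rectum_fill_scale > fb[2] + 1e-9)
    stop("fill scale outside the configured bounds")
  structure(list(fraction_index = as.integer(fraction_index),
                 prostate_shift = as.numeric(prostate_shift),
                 bladder_fill_scale = bladder_fill_scale,
                 rectum_fill_scale = rectum_fill_scale,
                 deformation_seed = as.integer(deformation_seed)),
            class = "fraction_scenario")
}

#' Draw one fraction scenario for a patient
#' @param template a `patient_template`.
#' @param fraction_index integer >= 1.
#' @param seed integer seed for this fraction.
#' @param params [cohort_params()].
#' @return a [fraction_scenario()].
#' @export
generate_scenario <- function(template, fraction_index, seed,
                              params = template$params) {
  set.seed(as.integer(seed))
  shift <- rnorm(3, 0, params$shift_sd)
  nrm <- sqrt(sum(shift^2))
  if (nrm > params$shift_cap) shift <- shift * params$shift_cap / nrm
  fb <- params$fill_bounds
  fills <- clamp(exp(rnorm(2, 0, c(params$fill_sdlog_bladder,
                                   params$fill_sdlog_rectum))), fb[1], fb[2])
  fraction_scenario(fraction_index, shift, fills[1], fills[2],
                    deformation_seed = derive_seed(seed, 77, fraction_index),
                    params = params)
}

# daily prostate semi-axis scales, drawn from the scenario's deformation seed
deform_scales <- function(scenario, params) {
  if (is.null(scenario) || !isTRUE(params$deform)) return(c(1, 1, 1))
  set.seed(scenario$deformation_seed)
  clamp(exp(rnorm(3, 0, params$deform_sdlog)),
        params$deform_bounds[1], params$deform_bounds[2])
}

#' Default lattice for a patient
#'
#' Covers every organ under worst-case shift, filling and deformation with
#' the configured padding (default 20 mm), snapped to the grid spacing.
#' @param template a `patient_template`.
#' @param params [cohort_params()].
#' @return a [grid_spec()].
#' @export
default_grid <- function(template, params = template$params) {
  fmax <- params$fill_bounds[2]^(1 / 3)
  dmax <- params$deform_bounds[2]
  cap <- params$shift_cap
  ax <- template$prostate_semiaxes * dmax + cap
  lo <- template$prostate_center - ax
  hi <- template$prostate_center + ax
  for (ctr in template$sv_centers) {
    lo <- pmin(lo, ctr + template$prostate_center - template$sv_semiaxes - cap)
    hi <- pmax(hi, ctr + template$prostate_center + template$sv_semiaxes + cap)
  }
  br <- template$bladder_base_radius * fmax
  lo <- pmin(lo, template$bladder_center - br)
  hi <- pmax(hi, template$bladder_center + br)
  rr <- template$rectum_base_radius * fmax
  lo <- pmin(lo, template$rectum_axis[1, ] - c(rr, rr, rr))
  hi <- pmax(hi, template$rectum_axis[2, ] + c(rr, rr, rr))
  lo <- lo - params$grid_padding
  hi <- hi + params$grid_padding
  sp <- params$grid_spacing
  origin <- floor(lo / sp) * sp
  dim <- ceiling((hi - origin) / sp) + 1
  grid_spec(sp, origin, dim)
}

ellipsoid_mask <- function(grid, center, semiaxes) {
  co <- grid_coords(grid)
  ux <- ((co$x - center[1]) / semiaxes[1])^2
  uy <- ((co$y - center[2]) / semiaxes[2])^2
  uz <- ((co$z - center[3]) / semiaxes[3])^2
  outer(outer(ux, uy, "+"), uz, "+") <= 1
}

capsule_mask <- function(grid, p1, p2, radius) {
  # vertical capsule: p1/p2 share x,y; hemispheric caps at the ends
  stopifnot(all(abs(p1[1:2] - p2[1:2]) < 1e-9))
  co <- grid_coords(grid)
  dxy <- outer((co$x - p1[1])^2, (co$y - p1[2])^2, "+")
  zlo <- min(p1[3], p2[3]); zhi <- max(p1[3], p2[3])
  dz <- (pmax(0, pmax(zlo - co$z, co$z - zhi)))^2
  outer(dxy, dz, "+") <= radius^2
}

#' Isotropic margin expansion of a binary mask
#'
#' Output voxels are those whose centre lies within `margin` mm (Euclidean)
#' of the input voxel set; the input is always contained in the output.
#'
#' @param mask logical 3D array.
#' @param margin mm, >= 0.
#' @param grid the mask's `grid_spec`.
#' @return logical 3D array.
#' @export
expand_margin <- function(mask, margin, grid) {
  if (!is.numeric(margin) || length(margin) != 1 || margin < 0)
    stop("margin must be a single non-negative number")
  if (margin == 0) return(mask)
  distance_to_mask(mask, grid) <= margin
}

#' Realize the structure set of a planning or fraction anatomy
#'
#' Voxelizes the template organs on the lattice (voxel-centre-inside rule).
#' For a fraction anatomy the prostate/SV are shifted rigidly, prostate
#' semi-axes scaled by the daily deformation draw, and bladder/rectum radii
#' scaled by the cube root of their fill scales.
#'
#' @param template a `patient_template`.
#' @param scenario a `fraction_scenario`, or `NULL` for the planning anatomy.
#' @param grid lattice; defaults to [default_grid()].
#' @param params [cohort_params()].
#' @return a [structure_set()] with masks prostate, sv, ctv, ptv, bladder,
#'   rectum.
#' @export
realize_structures <- function(template, scenario = NULL, grid = NULL,
                               params = template$params) {
  grid <- grid %||% default_grid(template, params)
  shift <- if (is.null(scenario)) c(0, 0, 0) else scenario$prostate_shift
  fills <- if (is.null(scenario)) c(1, 1)
           else c(scenario$bladder_fill_scale, scenario$rectum_fill_scale)
  scales <- deform_scales(scenario, params)

  pc <- template$prostate_center + shift
  psa <- template$prostate_semiaxes * scales
  br <- template$bladder_base_radius * fills[1]^(1 / 3)
  rr <- template$rectum_base_radius * fills[2]^(1 / 3)

  check_inside_grid(grid, pc, psa)
  check_inside_grid(grid, template$bladder_center, rep(br, 3))
  check_inside_grid(grid, template$rectum_axis[1, ], rep(rr, 3))
  check_inside_grid(grid, template$rectum_axis[2, ], rep(rr, 3))

  prostate <- ellipsoid_mask(grid, pc, psa)
  sv <- ellipsoid_mask(grid, template$sv_centers[[1]] + shift,
                       template$sv_semiaxes) |
        ellipsoid_mask(grid, template$sv_centers[[2]] + shift,
                       template$sv_semiaxes)
  co <- grid_coords(grid)
  below_cut <- rep(co$z <= template$sv_ctv_zcut + shift[3],
                   each = grid$dim[1] * grid$dim[2])
  ctv <- prostate | (sv & array(below_cut, grid$dim))
  ptv <- expand_margin(ctv, params$margin_mm, grid)
  bladder <- ellipsoid_mask(grid, template$bladder_center, rep(br, 3))
  rectum <- capsule_mask(grid, template$rectum_axis[1, ],
                         template$rectum_axis[2, ], rr)

  provenance <- if (is.null(scenario)) "planning"
                else sprintf("fraction %d", scenario$fraction_index)
  structure_set(list(prostate = prostate, sv = sv, ctv = ctv, ptv = ptv,
                     bladder = bladder, rectum = rectum),
                grid, provenance)
}

check_inside_grid <- function(grid, center, halfwidths) {
  lo <- grid$origin
  hi <- grid$origin + (grid$dim - 1) * grid$spacing
  if (any(center - halfwidths < lo) || any(center + halfwidths > hi))
    stop("grid too small: organ extends beyond the lattice")
  invisible(TRUE)
}

#' Rigid registration between planning and daily target
#'
#' Translation is the centroid difference daily - planning; rotation is zero
#' in the default translation-only mode. A principal-axes rotation estimate
#' is available behind `mode = "principal_axes"` (capped at +/- 10 degrees);
#' ellipsoid phantoms under-constrain rotation, so it is off by default.
#'
#' @param planning_ctv,daily_ctv logical CTV masks on a shared lattice.
#' @param grid the shared `grid_spec`.
#' @param mode `"translation"` (default) or `"principal_axes"`.
#' @return object of class `rigid_registration` with `translation` (mm) and
#'   `rotation` (degrees, XYZ).
#' @export
rigid_register <- function(planning_ctv, daily_ctv, grid,
                           mode = c("translation", "principal_axes")) {
  mode <- match.arg(mode)
  if (!any(planning_ctv) || !any(daily_ctv))
    stop("cannot register an empty mask")
  translation <- mask_centroid(daily_ctv, grid) -
                 mask_centroid(planning_ctv, grid)
  rotation <- c(0, 0, 0)
  if (mode == "principal_axes") {
    rotation <- principal_axes_rotation(planning_ctv, daily_ctv, grid)
    rotation <- clamp(rotation, -10, 10)
  }
  structure(list(translation = translation, rotation = rotation),
            class = "rigid_registration")
}

principal_axes_rotation <- function(planning_ctv, daily_ctv, grid) {
  axes <- function(mask) {
    idx <- which(mask, arr.ind = TRUE)
    xyz <- sweep(sweep(idx - 1, 2, grid$spacing, "*"), 2, grid$origin, "+")
    ev <- eigen(stats::cov(xyz), symmetric = TRUE)$vectors
    for (k in 1:3) if (ev[which.max(abs(ev[, k])), k] < 0) ev[, k] <- -ev[, k]
    ev
  }
  R <- axes(daily_ctv) %*% t(axes(planning_ctv))
  if (det(R) < 0) R[, 3] <- -R[, 3]
  # XYZ Euler angles in degrees
  ry <- asin(clamp(-R[3, 1], -1, 1))
  rx <- atan2(R[3, 2], R[3, 3])
  rz <- atan2(R[2, 1], R[1, 1])
  c(rx, ry, rz) * 180 / pi
}

#' @export
print.rigid_registration <- function(x, ...) {
  cat(sprintf("<rigid_registration> t = (%.2f, %.2f, %.2f) mm, r = (%.1f, %.1f, %.1f) deg\n",
              x$translation[1], x$translation[2], x$translation[3],
              x$rotation[1], x$rotation[2], x$rotation[3]))
  invisible(x)
}

#' Simulate a full synthetic cohort
#'
#' Patients x fractions are a pure function of `(master_seed, params)`;
#' per-patient and per-fraction seeds are hashed from the master seed and
#' the indices.
#'
#' @param n_patients,n_fractions cohort dimensions (paper-scale default is
#'   32 x 5; see [run_study()]).
#' @param master_seed integer master seed.
#' @param params [cohort_params()].
#' @param realize if `TRUE`, voxelize all structure sets and compute the
#'   per-fraction registrations (memory ~ O(patients x fractions x grid)).
#' @return list of class `synthetic_cohort`; one element per patient with
#'   `template`, `grid`, `planning` (structure set when realized) and
#'   `fractions` (scenario, structures, registration).
#' @export
simulate_cohort <- function(n_patients, n_fractions, master_seed = 1,
                            params = cohort_params(), realize = TRUE) {
  patients <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    tpl <- generate_patient(derive_seed(master_seed, i, 0), params,
                            patient_id = sprintf("P%02d", i))
    grid <- default_grid(tpl, params)
    planning <- if (realize) realize_structures(tpl, NULL, grid, params)
    fr <- vector("list", n_fractions)
    for (j in seq_len(n_fractions)) {
      sc <- generate_scenario(tpl, j, derive_seed(master_seed, i, j), params)
      if (realize) {
        ss <- realize_structures(tpl, sc, grid, params)
        reg <- rigid_register(planning$masks$ctv, ss$masks$ctv, grid)
        fr[[j]] <- list(scenario = sc, structures = ss, registration = reg)
      } else {
        fr[[j]] <- list(scenario = sc)
      }
    }
    patients[[i]] <- list(template = tpl, grid = grid,
                          planning = planning, fractions = fr)
  }
  structure(patients, class = "synthetic_cohort",
            master_seed = master_seed, params = params)
}
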