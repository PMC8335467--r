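test_that("conformal dose has an exact plateau and Gaussian falloff", {
  grid <- tiny_grid(24)
  ptv <- sphere_mask(grid, 10)
  par <- noiseless_params()
  d <- conformal_dose(ptv, grid, par, "ART3")  # conformity 0: pure falloff
  plateau <- par$prescription_ctv
  # deep interior voxel sits exactly at the plateau
  ci <- (grid$dim + 1) / 2
  expect_equal(d$values[ci[1], ci[2], ci[3]], plateau)
  # outside the PTV the closed form holds voxel-exactly, so the dose at
  # distance sigma is plateau * exp(-1/2)
  dist <- distance_to_mask(ptv, grid)
  sig <- par$penumbra_sigma[["ART3"]]
  sel <- dist > 0 & dist < 3 * sig
  expect_equal(d$values[sel],
               plateau * exp(-dist[sel]^2 / (2 * sig^2)), tolerance = 1e-12)
  # non-increasing along a ray leaving the PTV
  ray <- d$values[ci[1]:grid$dim[1], ci[2], ci[3]]
  expect_true(all(diff(ray) <= 1e-12))
  expect_error(conformal_dose(array(FALSE, grid$dim), grid, par, "ART1"),
               "empty")
})

test_that("noise field is positive with mean ~1 and set amplitude", {
  grid <- tiny_grid(20)
  f <- noise_field(grid, 0.02, 5, seed = 11)
  expect_true(all(f > 0))
  expect_lt(abs(mean(f) - 1), 0.01)
  expect_lt(abs(sd(f) - 0.02), 0.01)
  expect_identical(noise_field(grid, 0.02, 5, seed = 11), f)
})

test_that("oar_spare ramps only inside OARs beyond the interface shell", {
  grid <- tiny_grid(26)
  ptv <- sphere_mask(grid, 8)
  oar <- sphere_mask(grid, 8, center = c(0, -18, 0))
  par <- noiseless_params(oar_sparing_depth = 0.3)
  d <- conformal_dose(ptv, grid, par, "ART3")
  sp <- oar_spare(d, list(oar), ptv, par)
  # non-OAR voxels unchanged bit-exactly
  expect_identical(sp$values[!oar], d$values[!oar])
  # far OAR voxels (beyond 2 x margin) scaled by exactly 1 - depth
  dist <- distance_to_mask(ptv, grid)
  far <- oar & dist > 2 * par$oar_interface_margin
  expect_equal(sp$values[far], d$values[far] * 0.7)
  # inside the shell untouched
  shell <- oar & dist <= par$oar_interface_margin
  expect_identical(sp$values[shell], d$values[shell])
  # depth 0 is the identity
  par0 <- noiseless_params(oar_sparing_depth = 0)
  expect_identical(oar_spare(d, list(oar), ptv, par0)$values, d$values)
})

test_that("transform_dose is exact for identity and lattice-aligned shifts", {
  grid <- tiny_grid(20)
  ptv <- sphere_mask(grid, 8)
  d <- conformal_dose(ptv, grid, noiseless_params(), "REFERENCE")
  id <- transform_dose(d, identity_registration())
  expect_equal(id$values, d$values, tolerance = 1e-12)

  # one-voxel shift along y: interior voxels shift by one index
  reg <- structure(list(translation = c(0, 2, 0), rotation = c(0, 0, 0)),
                   class = "rigid_registration")
  sh <- transform_dose(d, reg)
  expect_equal(sh$values[, 2:20, ], d$values[, 1:19, ], tolerance = 1e-9)

  # integral dose preserved within 1% for interior sub-voxel shifts
  reg2 <- structure(list(translation = c(1.1, -0.7, 1.9),
                         rotation = c(0, 0, 0)),
                    class = "rigid_registration")
  sh2 <- transform_dose(d, reg2)
  expect_lt(abs(sum(sh2$values) / sum(d$values) - 1), 0.01)
  bad <- structure(list(translation = c(NA, 0, 0), rotation = c(0, 0, 0)),
                   class = "rigid_registration")
  expect_error(transform_dose(d, bad), "finite")
})

test_that("rescale_to_coverage pins D95(CTV) to the prescription", {
  grid <- tiny_grid(20)
  ctv <- sphere_mask(grid, 7)
  u <- uniform_dose(grid, 20)
  r <- rescale_to_coverage(u, ctv, 40, 95)
  expect_equal(unique(as.vector(r$values)), 40)

  set.seed(5)
  noisy <- dose_grid(array(runif(prod(grid$dim), 10, 45), grid$dim), grid)
  r2 <- rescale_to_coverage(noisy, ctv, 40, 95)
  expect_lt(abs(d_volume(r2, ctv, 95) - 40), 1e-6)
  # already-compliant input is a no-op
  r3 <- rescale_to_coverage(r2, ctv, 40, 95)
  expect_equal(r3$values, r2$values, tolerance = 1e-12)
  expect_error(rescale_to_coverage(uniform_dose(grid, 0), ctv), "zero")
})

test_that("make_plan wires the approaches per contract", {
  p <- .test_patient()
  par <- noiseless_params()
  cache <- new.env(parent = emptyenv())
  ref <- make_plan("REFERENCE", p$planning, p$planning,
                   identity_registration(), par, seed = 3, cache = cache)
  igrt <- make_plan("IGRT", p$planning, p$planning,
                    identity_registration(), par, seed = 3, cache = cache)
  # no deformation: IGRT reproduces the reference plan
  expect_equal(igrt$values, ref$values, tolerance = 1e-9)

  art1 <- make_plan("ART1", p$planning, p$planning,
                    identity_registration(), par, seed = 3, cache = cache)
  expect_lt(abs(d_volume(art1, p$planning$masks$ctv, 95) - 40), 1e-6)
  expect_gte(v_dose(art1, p$planning$masks$ctv, 40, "relative"), 94.5)

  # with zero noise and zero deformation all archetypes give the same CTV DVH
  art3 <- make_plan("ART3", p$planning, p$planning,
                    identity_registration(), par, seed = 3, cache = cache)
  for (d2 in list(art1, art3))
    expect_equal(sort(d2$values[p$planning$masks$ctv]),
                 sort(ref$values[p$planning$masks$ctv]), tolerance = 1e-9)

  # ART3 spares the bladder interior relative to ART1
  blad <- p$planning$masks$bladder
  dist <- distance_to_mask(p$planning$masks$ptv, p$grid)
  inner <- blad & dist > 2 * par$oar_interface_margin
  expect_lt(mean(art3$values[inner]), mean(art1$values[inner]))
  expect_error(make_plan("ART9", p$planning, p$planning,
                         identity_registration(), par), "arg")
})

test_that("dose model parameter ordering is validated", {
  expect_error(dose_model_params(penumbra_sigma = c(
    REFERENCE = 3, IGRT = 3, ART1 = 4, ART2 = 3.5, ART3 = 3)), "ART1")
  expect_error(dose_model_params(oar_sparing_depth = 1.5), "sparing")
  expect_error(dose_model_params(noise_amplitude = -0.1), "noise")
})
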