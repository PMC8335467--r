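test_that("patient generation is deterministic and validates parameters", {
  a <- generate_patient(7)
  b <- generate_patient(7)
  a$params <- b$params <- NULL
  expect_identical(a, b)
  expect_error(cohort_params(prostate_volume_sdlog = -1), "non-positive")
  expect_error(cohort_params(nonsense = 1), "unknown")
})

test_that("cohort prostate volumes reproduce the target spread", {
  # sample mean of the (analytic) ellipsoid volume over 200 patients must sit
  # within 65.3 +/- 10 cc; voxelization agrees with the analytic volume to 3%
  vols <- vapply(1:200, function(i) {
    tpl <- generate_patient(adaptrt:::derive_seed(123, i, 0))
    4 * pi / 3 * prod(tpl$prostate_semiaxes) / 1000
  }, numeric(1))
  expect_gt(mean(vols), 65.3 - 10)
  expect_lt(mean(vols), 65.3 + 10)
})

test_that("voxelized ellipsoid volume matches the closed form at 2 mm", {
  grid <- grid_spec(c(2, 2, 2), c(-40, -40, -40), c(41, 41, 41))
  m <- adaptrt:::ellipsoid_mask(grid, c(0, 0, 0), c(24, 20, 20))
  analytic <- 4 * pi / 3 * 24 * 20 * 20 / 1000   # 40.2 cc
  expect_lt(abs(sum(m) * voxel_volume_cc(grid) - analytic) / analytic, 0.03)
})

test_that("margin expansion matches analytic sphere growth and is monotone", {
  grid <- tiny_grid(24)
  s <- sphere_mask(grid, 10)
  expect_identical(expand_margin(s, 0, grid), s)
  grown <- expand_margin(s, 4, grid)
  expect_true(all(s[grown == FALSE] == FALSE))  # input subset of output
  expect_gte(sum(grown), sum(s))
  expect_error(expand_margin(s, -1, grid), "non-negative")

  # analytic oracle: measuring distances between voxel centres biases the
  # expanded surface inward by O(h), so the 5% closed-form check runs at
  # 0.5 mm where the discretization is converged
  gf <- tiny_grid(73, spacing = 0.5)
  sf <- sphere_mask(gf, 10)
  volf <- sum(expand_margin(sf, 4, gf)) * voxel_volume_cc(gf)
  analytic <- 4 * pi / 3 * 14^3 / 1000
  expect_lt(abs(volf - analytic) / analytic, 0.05)
})

test_that("structure realization honours identity and scaling scenarios", {
  p <- .test_patient()
  par0 <- cohort_params(deform = FALSE)
  base <- realize_structures(p$tpl, NULL, p$grid, par0)
  sc0 <- fraction_scenario(1, c(0, 0, 0), 1, 1, deformation_seed = 5,
                           params = par0)
  same <- realize_structures(p$tpl, sc0, p$grid, par0)
  expect_identical(base$masks, same$masks)

  # doubling the bladder fill doubles its voxelized volume (within 5%)
  sc2 <- fraction_scenario(1, c(0, 0, 0), 1.6, 1, deformation_seed = 5,
                           params = par0)
  v1 <- sum(base$masks$bladder)
  v2 <- sum(realize_structures(p$tpl, sc2, p$grid, par0)$masks$bladder)
  expect_lt(abs(v2 / v1 - 1.6), 0.05 * 1.6)

  # a +6 mm prostate shift moves the CTV centroid by +6 mm (within half a voxel)
  scs <- fraction_scenario(1, c(0, 6, 0), 1, 1, deformation_seed = 5,
                           params = par0)
  shifted <- realize_structures(p$tpl, scs, p$grid, par0)
  delta <- mask_centroid(shifted$masks$ctv, p$grid) -
           mask_centroid(base$masks$ctv, p$grid)
  expect_lt(max(abs(delta - c(0, 6, 0))), 1)
})

test_that("scenario invariants are enforced", {
  expect_error(fraction_scenario(1, c(0, 0, 20), 1, 1, 1), "cap")
  expect_error(fraction_scenario(1, c(0, 0, 0), 2.5, 1, 1), "bounds")
  expect_error(realize_structures(.test_patient()$tpl, NULL,
                                  grid_spec(c(2, 2, 2), c(0, 0, 0),
                                            c(10, 10, 10))),
               "grid too small")
})

test_that("CTV is contained in PTV and strictly smaller for a real margin", {
  p <- .test_patient()
  ss <- p$planning
  expect_false(any(ss$masks$ctv & !ss$masks$ptv))
  expect_gt(sum(ss$masks$ptv), sum(ss$masks$ctv))
})

test_that("PTV-OAR overlaps increase strictly with the fill scale", {
  p <- .test_patient()
  par0 <- cohort_params(deform = FALSE)
  fills <- c(0.8, 1.0, 1.2, 1.4, 1.6)
  ovl <- t(vapply(fills, function(f) {
    sc <- fraction_scenario(1, c(0, 0, 0), f, f, 1, params = par0)
    ss <- realize_structures(p$tpl, sc, p$grid, par0)
    c(overlap_volume(ss$masks$ptv, ss$masks$bladder, p$grid),
      overlap_volume(ss$masks$ptv, ss$masks$rectum, p$grid))
  }, numeric(2)))
  expect_true(all(diff(ovl[, 1]) > 0))
  expect_true(all(diff(ovl[, 2]) >= 0))  # rectum may touch late on the grid
  expect_gt(ovl[5, 2], ovl[1, 2])
})

test_that("rigid registration recovers constructed shifts", {
  grid <- tiny_grid(24)
  s <- sphere_mask(grid, 10)
  expect_equal(rigid_register(s, s, grid)$translation, c(0, 0, 0))

  # lattice-aligned constructed shift: (2, -4, 6) mm = (1, -2, 3) voxels
  sh <- sphere_mask(grid, 10, center = c(2, -4, 6))
  tr <- rigid_register(s, sh, grid)$translation
  expect_lt(max(abs(tr - c(2, -4, 6))), 1)

  # two single-voxel masks: translation equals the centre difference exactly
  a <- array(FALSE, grid$dim); a[5, 5, 5] <- TRUE
  b <- array(FALSE, grid$dim); b[8, 6, 9] <- TRUE
  expect_equal(rigid_register(a, b, grid)$translation, c(3, 1, 4) * 2)
  expect_error(rigid_register(a, array(FALSE, grid$dim), grid), "empty")
})

test_that("the cohort is a pure function of the master seed", {
  c1 <- simulate_cohort(2, 2, master_seed = 9)
  c2 <- simulate_cohort(2, 2, master_seed = 9)
  expect_identical(c1[[1]]$planning$masks, c2[[1]]$planning$masks)
  expect_identical(c1[[2]]$fractions[[2]]$scenario,
                   c2[[2]]$fractions[[2]]$scenario)
  expect_identical(c1[[2]]$fractions[[1]]$registration,
                   c2[[2]]$fractions[[1]]$registration)
  c3 <- simulate_cohort(2, 2, master_seed = 10)
  expect_false(identical(c1[[1]]$template$prostate_semiaxes,
                         c3[[1]]$template$prostate_semiaxes))
})
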