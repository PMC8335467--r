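test_that("penalty formula matches the stated arithmetic", {
  expect_equal(penalty_score(2.5, 2, "upper"), 25)
  expect_equal(penalty_score(34.0, 34.4, "lower"), abs((34 - 34.4) / 34.4) * 100)
  expect_equal(round(penalty_score(34.0, 34.4, "lower"), 4), 1.1628)
  expect_equal(round(penalty_score(92, 95, "lower"), 3), 3.158)
  # boundary convention: M = C is not exceeded
  expect_equal(penalty_score(2, 2, "upper"), 0)
  expect_equal(penalty_score(95, 95, "lower"), 0)
  expect_equal(penalty_score(1.2, 2, "upper"), 0)
  expect_error(penalty_score(1, 0, "upper"), "positive")
})

test_that("penalty is scale-invariant and monotone", {
  set.seed(1)
  for (i in 1:50) {
    M <- runif(1, 0, 50); C <- runif(1, 1, 40); k <- runif(1, 0.1, 10)
    for (dir in c("upper", "lower"))
      expect_equal(penalty_score(k * M, k * C, dir), penalty_score(M, C, dir))
  }
  Ms <- seq(0, 10, by = 0.5)
  up <- vapply(Ms, penalty_score, numeric(1), C = 4, direction = "upper")
  lo <- vapply(Ms, penalty_score, numeric(1), C = 4, direction = "lower")
  expect_true(all(diff(up) >= 0))
  expect_true(all(diff(lo) <= 0))
})

test_that("criterion evaluation assigns tiers and penalties", {
  grid <- tiny_grid(10)
  mask <- array(FALSE, grid$dim)
  mask[1:100] <- TRUE
  ss <- structure(list(masks = list(ptv = mask, ctv = mask, rectum = mask,
                                    bladder = mask),
                       grid = grid, provenance = "planning"),
                  class = "structure_set")
  crit <- pace_criteria()
  ptv_cov <- crit[crit$id == "V36.25Gy_PTV", ]

  vals <- rep(40, 100); vals[1:4] <- 0   # V36.25 = 96%
  r1 <- evaluate_criterion(masked_dose(grid, mask, vals), ss, ptv_cov)
  expect_equal(r1$tier, "optimal")
  expect_equal(r1$penalty, 0)

  vals[1:8] <- 0                          # 92%: minor band, penalized
  r2 <- evaluate_criterion(masked_dose(grid, mask, vals), ss, ptv_cov)
  expect_equal(r2$tier, "minor")
  expect_equal(round(r2$penalty, 3), 3.158)

  vals[1:15] <- 0                         # 85%: violation
  r3 <- evaluate_criterion(masked_dose(grid, mask, vals), ss, ptv_cov)
  expect_equal(r3$tier, "violation")

  # boundary: rectum V36 exactly at 2 cc is optimal (250 voxels = 2 cc)
  rec <- crit[crit$id == "V36Gy_rectum", ]
  m2 <- array(FALSE, grid$dim); m2[1:500] <- TRUE
  ss2 <- structure(list(masks = list(rectum = m2), grid = grid,
                        provenance = "planning"), class = "structure_set")
  v2 <- rep(0, 500); v2[1:250] <- 40
  r4 <- evaluate_criterion(masked_dose(grid, m2, v2), ss2, rec)
  expect_equal(r4$measured, 2)
  expect_equal(r4$tier, "optimal")
  expect_error(evaluate_criterion(masked_dose(grid, m2, v2), ss2,
                                  crit[crit$id == "V37Gy_bladder", ]),
               "missing")
})

test_that("plan penalty sums the four scored criteria only", {
  mk <- function(id, pen, in_pen = TRUE)
    data.frame(id = id, structure = "x", measured = 1, bound = 1,
               direction = "upper", tier = "violation", penalty = pen,
               in_penalty = in_pen)
  res <- rbind(mk("V36.25Gy_PTV", 3.158), mk("D98pct_PTV", 0),
               mk("V37Gy_bladder", 25), mk("V36Gy_rectum", 0))
  expect_equal(plan_penalty(res), 28.158)
  # adding a satisfied reporting criterion leaves S unchanged
  res2 <- rbind(res, mk("V40Gy_CTV", 99, in_pen = FALSE),
                mk("V29Gy_rectum", 7, in_pen = FALSE))
  expect_equal(plan_penalty(res2), 28.158)
  expect_equal(plan_penalty(rbind(mk("V36.25Gy_PTV", 0), mk("D98pct_PTV", 0),
                                  mk("V37Gy_bladder", 0),
                                  mk("V36Gy_rectum", 0))), 0)
  expect_error(plan_penalty(res[-1, ]), "missing")
})

test_that("S = 0 iff all four scored criteria are met (property)", {
  set.seed(7)
  ids <- adaptrt:::penalty_criterion_ids()
  for (i in 1:30) {
    pens <- ifelse(runif(4) < 0.5, 0, runif(4, 0.1, 40))
    res <- data.frame(id = ids, structure = "x", measured = 1, bound = 1,
                      direction = "upper", tier = "optimal",
                      penalty = pens, in_penalty = TRUE)
    S <- plan_penalty(res)
    expect_equal(S == 0, all(pens == 0))
    expect_equal(S, sum(pens))
  }
})

test_that("cohort penalty table aggregates both summations consistently", {
  # random synthetic evaluation grid: 3 patients x 2 fractions x 2 approaches
  set.seed(11)
  ids <- adaptrt:::penalty_criterion_ids()
  rows <- expand.grid(patient = c("P1", "P2", "P3"), fraction = 1:2,
                      approach = c("IGRT", "ART3"), id = ids,
                      stringsAsFactors = FALSE)
  rows$penalty <- round(runif(nrow(rows), 0, 30), 3)
  rows$in_penalty <- TRUE
  S <- aggregate(penalty ~ patient + fraction + approach, rows, sum)
  rows$S <- S$penalty[match(paste(rows$patient, rows$fraction, rows$approach),
                            paste(S$patient, S$fraction, S$approach))]
  pt <- cohort_penalty_table(rows)
  # column totals equal the sum of the per-criterion entries
  expect_equal(colSums(pt$per_criterion), pt$totals)
  # totals also equal the direct sum over all plans
  expect_equal(unname(pt$totals["IGRT"]),
               sum(rows$penalty[rows$approach == "IGRT"]))
  # cohort mean is the arithmetic mean of the per-patient means
  expect_equal(colMeans(pt$per_patient_mean), pt$cohort_mean)
  # per-patient mean x fractions recovers the patient total
  expect_equal(sum(pt$per_patient_mean[, "ART3"]) * 2,
               sum(rows$penalty[rows$approach == "ART3"]))
  expect_error(cohort_penalty_table(rows[-(1:4), ]), "full")
})

test_that("singleton plans report SD 0", {
  ids <- adaptrt:::penalty_criterion_ids()
  one <- data.frame(patient = "P1", fraction = 1, approach = "IGRT",
                    id = ids, penalty = c(25, 0, 0, 0), in_penalty = TRUE,
                    S = 25)
  pt <- cohort_penalty_table(one)
  expect_equal(unname(pt$per_patient_mean[1, 1]), 25)
  expect_equal(unname(pt$per_patient_sd[1, 1]), 0)
})

test_that("percent reduction reproduces printed arithmetic", {
  expect_equal(percent_reduction(100, 100), 0)
  expect_equal(percent_reduction(624, 9139), 93.2)
  expect_equal(percent_reduction(92, 1800), 94.9)
  expect_true(is.na(percent_reduction(5, 0)))
})

test_that("criteria config round-trips through CSV", {
  cr <- pace_criteria()
  expect_equal(nrow(cr), 12)
  expect_equal(sort(cr$id[cr$in_penalty]),
               sort(adaptrt:::penalty_criterion_ids()))
  f <- tempfile(fileext = ".csv")
  write.csv(cr, f, row.names = FALSE)
  expect_equal(pace_criteria(f)$bound, cr$bound)
  # malformed config is rejected
  bad <- cr; bad$bound[1] <- -1
  write.csv(bad, f, row.names = FALSE)
  expect_error(pace_criteria(f), "non-positive")
})
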