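test_that("psychometric observers respect chance and lapse bounds", {
  obs <- psychometric_observer(10, beta = 0.6, lapse = 0.05)
  p <- vapply(tdd_series(), obs, numeric(1))
  expect_true(all(p >= 0.5 & p <= 0.95))
  expect_true(all(diff(p) > 0))  # longer distances are easier
  expect_equal(obs(10), 0.5 + 0.45 * 0.5)  # inflection at alpha
  wb <- psychometric_observer(10, form = "weibull")
  expect_true(all(vapply(tdd_series(), wb, numeric(1)) >= 0.5))
  expect_error(psychometric_observer(10, lapse = 0.2), "lapse")
  expect_error(psychometric_observer(-1), "alpha")
})

test_that("normative cohorts are reproducible, in range, and carry the age effect", {
  a <- simulate_normative_cohort(site = "foot", seed = 99)
  b <- simulate_normative_cohort(site = "foot", seed = 99)
  expect_identical(a, b)
  expect_equal(nrow(a), 43)  # site default sample size
  expect_true(all(a$raw_score >= 18 & a$raw_score <= 186))
  expect_true(all(a$age >= 22 & a$age <= 68))
  expect_equal(nrow(simulate_normative_cohort(site = "hand", seed = 1)), 34)

  # with the age effect disabled the fitted threshold slope is ~0
  flat_scores <- simulate_normative_cohort(n = 120, site = "foot",
                                           age_factor = 1, seed = 3)
  thr <- fit_linear_threshold(flat_scores)
  expect_lt(abs(thr$slope), 0.5)
})

test_that("the injected foot age slope is recovered by regression", {
  set.seed(17)
  slopes <- vapply(1:12, function(i) {
    s <- simulate_normative_cohort(n = 60, site = "foot", seed = 1000 + i)
    age_effect_test(s)$slope
  }, numeric(1))
  # generator is calibrated for an emergent ~1.2 points/year
  expect_equal(mean(slopes), 1.2, tolerance = 0.35)
  sig <- vapply(1:6, function(i) {
    s <- simulate_normative_cohort(n = 60, site = "foot", seed = 2000 + i)
    age_effect_test(s)$p.value < 0.05
  }, logical(1))
  expect_true(all(sig))
})

test_that("phantom parcellations have the constructed sizes and reject overlap", {
  shapes <- list(
    list(label = 1L, type = "cuboid", corner = c(1, 1, 1), size = c(6, 6, 6)),
    list(label = 2L, type = "cuboid", corner = c(10, 1, 1), size = c(6, 6, 6)),
    list(label = 3L, type = "cuboid", corner = c(1, 10, 1), size = c(4, 4, 4)))
  v <- make_phantom_parcellation(c(16, 16, 16), shapes)
  sp <- split_into_contiguous_nodes(v)
  expect_equal(sp$table$n_voxels, c(216, 216, 64))

  # a node of exactly 100 voxels is built but fails eligibility
  v100 <- make_phantom_parcellation(c(12, 12, 12), list(
    list(label = 1L, type = "cuboid", corner = c(1, 1, 1), size = c(5, 5, 4))))
  sp100 <- split_into_contiguous_nodes(v100)
  expect_equal(sp100$table$n_voxels, 100)
  expect_equal(nrow(eligible_nodes(sp100$table, node_criteria())), 0)

  overlapping <- list(
    list(label = 1L, type = "cuboid", corner = c(1, 1, 1), size = c(4, 4, 4)),
    list(label = 2L, type = "cuboid", corner = c(3, 3, 3), size = c(4, 4, 4)))
  expect_error(make_phantom_parcellation(c(10, 10, 10), overlapping),
               "overlap")
  expect_error(make_phantom_parcellation(c(5, 5, 5), list(
    list(label = 1L, type = "cuboid", corner = c(4, 4, 4), size = c(4, 4, 4)))),
    "outside")
  expect_equal(sum(make_phantom_parcellation(c(5, 5, 5), list())), 0)

  sph <- make_phantom_parcellation(c(15, 15, 15), list(
    list(label = 1L, type = "sphere", center = c(8, 8, 8), radius = 4)))
  expect_gt(sum(sph == 1), 0)
})

test_that("patient cohorts are seeded, structured, and carry ground truth", {
  a <- simulate_patient_cohort(seed = 41)
  b <- simulate_patient_cohort(seed = 41)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$lesions, b$lesions)
  expect_equal(nrow(a$cohort), 28)
  expect_equal(length(a$ground_truth$lesioned), round(0.3 * 28))
  expect_identical(a$cohort$target,
                   seq_len(28) %in% a$ground_truth$lesioned)

  # large effect: every deficit-lesioned patient is impaired on the left
  big <- simulate_patient_cohort(effect_size = 6, seed = 13)
  cls <- classify_cohort(big$cohort, "followup")
  expect_true(all(cls$abnormal[big$ground_truth$lesioned]))

  # full mode produces valid relative scores from real staircases
  full <- simulate_patient_cohort(n_patients = 4, n_lesioned = 2,
                                  mode = "full", seed = 3)
  rel <- unlist(full$cohort[, c("rh_3m", "lh_3m", "rf_3m", "lf_3m")])
  expect_true(all(is.finite(rel)))
  expect_true(all(rel > -1))  # raw scores >= 18 keep relative scores above -1
})

test_that("a null cohort yields roughly uniform association p-values", {
  spec <- phantom_default_spec()
  parc <- make_phantom_parcellation(spec$grid, spec$shapes)
  sp <- split_into_contiguous_nodes(parc)
  ps <- vapply(1:60, function(i) {
    s <- simulate_patient_cohort(effect_size = 0, nodes = sp, seed = 5000 + i)
    target_area_association(s$cohort)$p.value
  }, numeric(1))
  # discrete conservative p-values: no excess of small values under the null
  expect_lt(mean(ps < 0.05), 0.12)
  expect_gt(mean(ps > 0.5), 0.3)
})

test_that("the packaged patient table matches its printed values", {
  co <- table2_fixture()
  expect_equal(nrow(co), 28)
  expect_equal(co$lh_3m[co$patient == 8], 4.96)
  expect_equal(co$rh_acute[co$patient == 8], -0.35)
  p25 <- co[co$patient == 25, c("rh_3m", "lh_3m", "rf_3m", "lf_3m")]
  expect_true(all(p25 < 0))
  expect_equal(sum(co$target), 9)
  expect_true(co$sd_rf_3m[co$patient == 6])
  expect_true(all(co$sd_rf_acute[co$patient %in% c(20, 21)]))
  expect_equal(sum(co$sd_rf_3m), 3)
  expect_equal(co$rf_3m[co$patient == 1], 0)
})
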