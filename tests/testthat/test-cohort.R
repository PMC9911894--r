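test_that("the default spec encodes the documented cohort structure", {
  sp <- default_cohort_spec()
  expect_s3_class(sp, "cohort_spec")
  expect_equal(sum(sp$cytology_class_probs), 1, tolerance = 1e-12)
  expect_equal(unname(sp$malignancy_prob_given_class["TIR2"]), 0)
  expect_equal(unname(sp$malignancy_prob_given_class["TIR5"]), 1)
  for (v in sp$us_feature_prevalences) {
    expect_equal(sum(v), 1, tolerance = 1e-9)
  }
  expect_silent(validate_cohort_spec(sp))
})

test_that("spec validation names the offending field", {
  sp <- default_cohort_spec()
  sp$cytology_class_probs["TIR2"] <- 0.9
  expect_error(validate_cohort_spec(sp), "cytology_class_probs")
  sp2 <- default_cohort_spec(n_patients = 500L)
  expect_error(validate_cohort_spec(sp2), "n_patients")
  expect_error(default_cohort_spec(not_a_field = 1), "not_a_field")
})

test_that("conditional feature distributions preserve the marginals", {
  sp <- default_cohort_spec()
  pi_mal <- expected_malignancy_prob(sp)
  cond <- conditional_feature_probs(sp)
  for (f in names(sp$us_feature_prevalences)) {
    mix <- pi_mal * cond$malignant[[f]] + (1 - pi_mal) * cond$benign[[f]]
    expect_equal(mix, sp$us_feature_prevalences[[f]], tolerance = 1e-8)
    expect_true(all(cond$malignant[[f]] >= 0) && all(cond$benign[[f]] >= 0))
  }
  # the tilt raises every suspicious token in the malignant stratum
  expect_gt(cond$malignant$echogenicity[["very_hypoechoic"]],
            cond$benign$echogenicity[["very_hypoechoic"]])
  expect_gt(cond$malignant$echogenic_foci[["microcalcification"]],
            cond$benign$echogenic_foci[["microcalcification"]])
})

test_that("generation is deterministic given the seed", {
  a <- generate_cohort(default_cohort_spec(), n_nodules = 120, seed = 17)
  b <- generate_cohort(default_cohort_spec(), n_nodules = 120, seed = 17)
  expect_identical(a, b)
  c2 <- generate_cohort(default_cohort_spec(), n_nodules = 120, seed = 18)
  expect_false(identical(a, c2))
})

test_that("generated cohorts validate and respect structural bounds", {
  co <- generate_cohort(default_cohort_spec(), n_nodules = 400, seed = 2)
  expect_length(validate_cohort(co), 0)
  expect_true(all(co$major_diameter_mm >= 4 & co$major_diameter_mm <= 62))
  expect_equal(length(unique(co$patient_id)),
               max(1L, as.integer(round(112 * 400 / 188))))
  # every patient's clinical flags are shared across their nodules
  split_fam <- tapply(co$family_history_thyroid_cancer, co$patient_id,
                      function(x) length(unique(x)))
  expect_true(all(split_fam == 1))
})

test_that("class frequencies and malignancy rates are recovered at scale", {
  sp <- default_cohort_spec()
  co <- generate_cohort(sp, n_nodules = 4e4, seed = 23)
  n <- nrow(co)
  for (cls in names(sp$cytology_class_probs)) {
    p <- sp$cytology_class_probs[[cls]]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(co$cytology == cls) - p), 4 * se + 1e-12)
  }
  for (cls in c("TIR3A", "TIR3B", "TIR4")) {
    idx <- co$cytology == cls
    p <- sp$malignancy_prob_given_class[[cls]]
    se <- sqrt(p * (1 - p) / sum(idx))
    expect_lt(abs(mean(co$malignant[idx]) - p), 4 * se)
  }
  expect_true(all(!co$malignant[co$cytology == "TIR2"]))
  expect_true(all(co$malignant[co$cytology == "TIR5"]))
})

test_that("malignant nodules look more suspicious than benign ones", {
  co <- generate_cohort(default_cohort_spec(), n_nodules = 2e4, seed = 29)
  pts <- tirads_points(co$composition, co$echogenicity, co$shape,
                       co$margins, co$echogenic_foci)$points
  expect_gt(mean(pts[co$malignant]), mean(pts[!co$malignant]))
})

test_that("histologic diameters shrink and track ultrasound diameters", {
  co <- generate_cohort(default_cohort_spec(), n_nodules = 4e4, seed = 31)
  ok <- !is.na(co$histologic_diameter_mm)
  expect_gt(mean(ok), 0.6)
  expect_lt(median(co$histologic_diameter_mm[ok] / co$major_diameter_mm[ok]), 1)
  r <- cor(co$major_diameter_mm[ok], co$histologic_diameter_mm[ok])
  expect_lt(abs(r - 0.8), 0.05)
})
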