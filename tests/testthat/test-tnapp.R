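test_that("applicability exclusions are detected with reasons", {
  a <- tnapp_applicability("pet_positive_nodule", NA)
  expect_false(a$applicable)
  expect_equal(a$reasons, "pet_positive_nodule")
  expect_true(tnapp_applicability("", NA)$applicable)
  # hereditary predisposing syndrome (Gardner, Cowden, ...) excludes
  expect_false(tnapp_applicability("hereditary_syndrome", NA)$applicable)
  # mildly elevated calcitonin crosses the 10 pg/mL threshold
  b <- tnapp_applicability("", 14.5)
  expect_false(b$applicable)
  expect_match(b$reasons, "elevated_calcitonin")
  expect_true(tnapp_applicability("", 7.2)$applicable)
})

test_that("decision layers fire in the documented order", {
  # size above 20 mm alone suggests biopsy whatever the class
  d <- tnapp_assess(toy_nodule(major_diameter_mm = 22))
  expect_equal(d$base_us_class, "US2")
  expect_equal(d$action, "fna_suggested")

  # elevated calcitonin dominates everything
  d <- tnapp_assess(toy_nodule(calcitonin_pg_per_mL = 784,
                               major_diameter_mm = 30))
  expect_equal(d$action, "excluded")
  expect_match(d$fired_rules, "elevated_calcitonin")

  # high-risk ultrasound at 12 mm is recommended, with or without clinic
  hi <- toy_nodule(echogenicity = "very_hypoechoic", major_diameter_mm = 12,
                   favoring_fna = "hard_or_fixed_consistency")
  d <- tnapp_assess(hi)
  expect_equal(d$action, "fna_recommended")
  expect_match(d$fired_rules, "us3_high_risk_size")

  # favoring factor upgrades a size-based suggestion to a recommendation
  d <- tnapp_assess(toy_nodule(major_diameter_mm = 22,
                               favoring_fna = "compressive_symptoms"))
  expect_equal(d$action, "fna_recommended")

  # against factor downgrades a suggestion to follow-up
  d <- tnapp_assess(toy_nodule(major_diameter_mm = 22,
                               against_fna = "pregnancy"))
  expect_equal(d$action, "no_fna_followup")

  # favoring beats against when both are present
  d <- tnapp_assess(toy_nodule(major_diameter_mm = 22,
                               favoring_fna = "compressive_symptoms",
                               against_fna = "pregnancy"))
  expect_equal(d$action, "fna_recommended")

  # sub-5 mm nodules are follow-up regardless of features
  d <- tnapp_assess(toy_nodule(echogenicity = "very_hypoechoic",
                               margins = "spiculated_sharp_angles",
                               major_diameter_mm = 4.5))
  expect_equal(d$action, "no_fna_followup")
  # ... even when a favoring clinical factor would otherwise upgrade
  d <- tnapp_assess(toy_nodule(major_diameter_mm = 4.5,
                               favoring_fna = "compressive_symptoms"))
  expect_equal(d$action, "no_fna_followup")
  expect_match(d$fired_rules, "small_nodule_override")
})

test_that("missing ultrasound fields raise an incomplete-record error", {
  co <- toy_nodule()
  co$margins <- NULL
  expect_error(tnapp_assess(co), "margins")
  co2 <- toy_nodule(); co2$major_diameter_mm <- NA_real_
  expect_error(tnapp_assess(co2), "major_diameter_mm")
})

test_that("exclusions dominate every ultrasound configuration", {
  co <- random_us_cohort(400, seed = 7)
  excl <- nodule_vocab()$exclusions
  set.seed(8)
  co$exclusions <- sample(excl, nrow(co), replace = TRUE)
  d <- tnapp_assess(co)
  expect_true(all(d$action == "excluded"))
  expect_true(all(is.na(tnapp_binary(d$action))))
})

test_that("against-factors never turn a follow-up into a biopsy", {
  co <- random_us_cohort(300, seed = 11)
  base <- tnapp_assess(co)
  co2 <- co
  set.seed(12)
  co2$against_fna <- sample(nodule_vocab()$against_fna, nrow(co2),
                            replace = TRUE)
  mod <- tnapp_assess(co2)
  no_fna <- base$action == "no_fna_followup"
  expect_true(all(mod$action[no_fna] == "no_fna_followup"))
})

test_that("the audit trail is deterministic and non-empty", {
  co <- random_us_cohort(100, seed = 21)
  a <- tnapp_assess(co)
  b <- tnapp_assess(co)
  expect_identical(a, b)
  expect_true(all(nzchar(a$fired_rules)))
})

test_that("us_only mode equals the default on clinically silent records", {
  co <- random_us_cohort(200, seed = 31)
  cfg <- tnapp_config(); cfg$us_only <- TRUE
  expect_identical(tnapp_assess(co, cfg)$action, tnapp_assess(co)$action)
})

test_that("binary TNAPP agrees with the AACE indication on silent records", {
  # with no clinical factors, TNAPP's perform/avoid split reduces to the
  # AACE ultrasound/size rule
  co <- random_us_cohort(500, seed = 41)
  tn <- tnapp_binary(tnapp_assess(co)$action)
  aa <- aace_assess(co)$action == "fna_recommended"
  expect_identical(tn, aa)
})
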