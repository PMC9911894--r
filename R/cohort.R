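#' Generative specification of a synthetic nodule cohort
#'
#' Defaults emulate the statistical structure of a surgical thyroid-nodule
#' series: 188 nodules in 112 patients; cytology class frequencies of
#' 6.4/25/12.8/23.4/10.1/22.3% for TIR1..TIR5 (TIR3 split into A/B);
#' class-conditional malignancy rates of 25/0/29/36/63/100%; ultrasound
#' descriptor prevalences matching the leading-characteristic marginals of
#' such a cohort; a clamped lognormal diameter distribution with median
#' 14 mm on [4, 62]; and a multiplicative histology-diameter noise model
#' (0.9 shrinkage scale after formalin fixation) calibrated so ultrasound
#' and histologic diameters correlate at Pearson r of about 0.8.
#'
#' Generation order: cytology class first, malignancy conditional on class,
#' then ultrasound descriptors conditional on malignancy. Because only
#' marginal descriptor prevalences are known, the malignant/benign
#' conditional distributions are built as a mixture that tilts suspicious
#' tokens by `suspicious_feature_enrichment_odds` while preserving the
#' marginals exactly; odds are shrunk per feature when the requested tilt
#' would force a negative benign-cell probability.
#'
#' @param ... Named overrides of any default field.
#' @return An object of class `cohort_spec`.
#' @export
#' @examples
#' sp <- default_cohort_spec()
#' sum(sp$cytology_class_probs)  # 1
default_cohort_spec <- function(...) {
  spec <- list(
    n_nodules = 188L,
    n_patients = 112L,
    cytology_class_probs = c(TIR1 = 0.064, TIR2 = 0.25, TIR3A = 0.128,
                             TIR3B = 0.234, TIR4 = 0.101, TIR5 = 0.223),
    malignancy_prob_given_class = c(TIR1 = 0.25, TIR2 = 0, TIR3A = 0.29,
                                    TIR3B = 0.36, TIR4 = 0.63, TIR5 = 1),
    us_feature_prevalences = list(
      composition = c(purely_cystic = 3, spongiform = 0,
                      mixed_cystic_solid = 11, solid = 174) / 188,
      echogenicity = c(anechoic = 4, hyperechoic = 5, isoechoic = 59,
                       hypoechoic = 73, very_hypoechoic = 48) / 189,
      shape = c(oval_or_round = 167, taller_than_wide = 21) / 188,
      margins = c(smooth_or_regular = 134, ill_defined = 13,
                  irregular_protrusion = 15, spiculated_sharp_angles = 26) / 188,
      echogenic_foci = c(none = 126, difficult_to_characterize = 17,
                         macrocalcification = 10, peripheral_calcification = 4,
                         microcalcification = 35) / 192,
      vascular_pattern = c(peripheral_or_low = 131, intranodular = 57) / 188
    ),
    suspicious_feature_enrichment_odds = c(very_hypoechoic = 3,
                                           taller_than_wide = 3,
                                           spiculated_sharp_angles = 3,
                                           microcalcification = 3),
    diameter_log_mean = log(14),
    diameter_log_sd = 0.55,
    diameter_min_mm = 4,
    diameter_max_mm = 62,
    histology_shrinkage_scale = 0.9,
    histology_diameter_noise_sd = 0.36,
    histology_diameter_missing_prob = 55 / 188,
    tsh_log_median = log(1.89),
    tsh_log_sd = 0.6,
    calcitonin_measured_prob = 0.34,
    clinical_factor_probs = list(
      favoring = c(hard_or_fixed_consistency = 0.10,
                   head_neck_irradiation_history = 0.01,
                   compressive_symptoms = 0.08,
                   documented_sudden_enlargement = 0.02,
                   cancer_rule_out_protocol = 0.01,
                   planned_thyroid_or_parathyroid_surgery = 0.02),
      against = c(low_tsh_untreated = 0.02,
                  limited_life_expectancy_or_comorbidity = 0.03,
                  prior_lobectomy_vocal_cord_paralysis = 0.005,
                  pregnancy = 0.01,
                  hyperfunctioning_autonomous_nodule = 0.02,
                  prior_benign_cytology_same_nodule = 0.05),
      exclusions = c(prior_thyroid_cancer = 0, hereditary_syndrome = 0,
                     pet_positive_nodule = 0, elevated_calcitonin = 0,
                     suspicious_regional_adenopathy = 0)
    ),
    family_history_prob = 0.03,
    personal_history_prob = 0,
    pathologic_adenopathy_prob = 0,
    tpo_ab_elevated_prob = 0.28,
    on_levothyroxine_prob = 0.26,
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(spec))
  if (length(unknown)) {
    stop("unknown cohort_spec field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  spec[names(dots)] <- dots
  structure(spec, class = "cohort_spec")
}

#' Validate a cohort specification
#' @param spec A `cohort_spec`.
#' @return Invisibly, the spec; stops with the offending field otherwise.
#' @export
validate_cohort_spec <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  fail <- function(field) stop("invalid cohort_spec field: ", field, call. = FALSE)
  if (spec$n_nodules < 1) fail("n_nodules")
  if (spec$n_patients < 1 || spec$n_patients > spec$n_nodules) fail("n_patients")
  if (abs(sum(spec$cytology_class_probs) - 1) > 1e-9) fail("cytology_class_probs")
  if (any(spec$cytology_class_probs < 0)) fail("cytology_class_probs")
  p <- spec$malignancy_prob_given_class
  if (any(p < 0 | p > 1)) fail("malignancy_prob_given_class")
  voc <- nodule_vocab()
  for (f in names(spec$us_feature_prevalences)) {
    v <- spec$us_feature_prevalences[[f]]
    if (!setequal(names(v), voc[[f]])) fail(paste0("us_feature_prevalences$", f))
    if (abs(sum(v) - 1) > 1e-9 || any(v < 0)) {
      fail(paste0("us_feature_prevalences$", f))
    }
  }
  if (any(spec$suspicious_feature_enrichment_odds <= 0)) {
    fail("suspicious_feature_enrichment_odds")
  }
  if (spec$diameter_min_mm <= 0 || spec$diameter_max_mm <= spec$diameter_min_mm) {
    fail("diameter_min_mm/diameter_max_mm")
  }
  probs <- c(unlist(spec$clinical_factor_probs), spec$family_history_prob,
             spec$personal_history_prob, spec$pathologic_adenopathy_prob,
             spec$tpo_ab_elevated_prob, spec$on_levothyroxine_prob,
             spec$histology_diameter_missing_prob, spec$calcitonin_measured_prob)
  if (any(probs < 0 | probs > 1)) fail("a probability outside [0, 1]")
  invisible(spec)
}

#' Overall malignancy probability implied by a spec
#' @param spec A `cohort_spec`.
#' @return Scalar probability.
#' @export
expected_malignancy_prob <- function(spec) {
  sum(spec$cytology_class_probs * spec$malignancy_prob_given_class)
}

#' Malignant/benign conditional descriptor distributions of a spec
#'
#' Tilts each suspicious token's probability by its enrichment odds in the
#' malignant stratum and solves the benign stratum from the mixture identity
#' `marginal = pi * malignant + (1 - pi) * benign`, so marginal prevalences
#' are preserved exactly. When the requested odds would drive a benign cell
#' negative, the tilt is shrunk to the largest feasible value for that
#' feature.
#'
#' @param spec A `cohort_spec`.
#' @return List with elements `malignant` and `benign`, each a list of named
#'   probability vectors per descriptor.
#' @export
conditional_feature_probs <- function(spec) {
  pi_mal <- expected_malignancy_prob(spec)
  odds <- spec$suspicious_feature_enrichment_odds
  out <- list(malignant = list(), benign = list())
  for (f in names(spec$us_feature_prevalences)) {
    p <- spec$us_feature_prevalences[[f]]
    o <- rep(1, length(p)); names(o) <- names(p)
    shared <- intersect(names(p), names(odds))
    o[shared] <- odds[shared]
    w <- p * o
    p_full <- w / sum(w)
    # shrink the tilt so the benign stratum stays a valid distribution
    up <- p_full > p & p > 0
    lam <- 1
    if (pi_mal > 0 && any(up)) {
      lam <- min(1, 0.99 * min(p[up] * (1 - pi_mal) /
                                 (pi_mal * (p_full[up] - p[up]))))
    }
    p_mal <- (1 - lam) * p + lam * p_full
    p_ben <- if (pi_mal < 1) pmax((p - pi_mal * p_mal) / (1 - pi_mal), 0) else p
    p_ben <- p_ben / sum(p_ben)
    out$malignant[[f]] <- p_mal
    out$benign[[f]] <- p_ben
  }
  out
}

.sample_cat <- function(n, probs) {
  names(probs)[sample.int(length(probs), n, replace = TRUE, prob = probs)]
}

.benign_labels <- c("goiter", "adenoma", "thyroiditis", "goiter_and_thyroiditis",
                    "cystic")
.malignant_labels <- c("papillary_cancer", "follicular_cancer", "medullary_cancer")

#' Generate a synthetic nodule cohort
#'
#' Deterministic given `spec$seed`. See [default_cohort_spec()] for the
#' generative model and its defaults.
#'
#' @param spec A `cohort_spec`; validated before use.
#' @param n_nodules Optional override of `spec$n_nodules` (patients are
#'   scaled proportionally).
#' @param seed Optional override of `spec$seed`.
#' @return A data frame in the canonical cohort schema
#'   (see [cohort_columns()]), one row per nodule, with cytology, malignancy
#'   truth and histologic diameters filled in.
#' @export
#' @examples
#' cohort <- generate_cohort(default_cohort_spec(), n_nodules = 50, seed = 7)
#' nrow(cohort)
generate_cohort <- function(spec = default_cohort_spec(), n_nodules = NULL,
                            seed = NULL) {
  if (!is.null(n_nodules)) {
    spec$n_patients <- max(1L, as.integer(round(
      spec$n_patients * n_nodules / spec$n_nodules)))
    spec$n_nodules <- as.integer(n_nodules)
  }
  if (!is.null(seed)) spec$seed <- seed
  validate_cohort_spec(spec)
  set.seed(spec$seed)

  n <- spec$n_nodules
  npat <- spec$n_patients

  # patients: every patient carries at least one nodule; the surplus is
  # spread at random so some patients carry several
  pat_of <- c(seq_len(npat), sample.int(npat, n - npat, replace = TRUE))
  pat_of <- sample(pat_of)

  # patient-level clinical state
  draw_set <- function(probs, m) {
    lapply(seq_len(m), function(i) names(probs)[stats::runif(length(probs)) < probs])
  }
  fav_p <- draw_set(spec$clinical_factor_probs$favoring, npat)
  agn_p <- draw_set(spec$clinical_factor_probs$against, npat)
  exc_p <- draw_set(spec$clinical_factor_probs$exclusions, npat)
  famhist_p <- stats::runif(npat) < spec$family_history_prob
  pershist_p <- stats::runif(npat) < spec$personal_history_prob
  aden_p <- stats::runif(npat) < spec$pathologic_adenopathy_prob
  tpo_p <- stats::runif(npat) < spec$tpo_ab_elevated_prob
  lt4_p <- stats::runif(npat) < spec$on_levothyroxine_prob
  tsh_p <- pmin(pmax(stats::rlnorm(npat, spec$tsh_log_median, spec$tsh_log_sd),
                     0.3), 9)
  calc_measured <- stats::runif(npat) < spec$calcitonin_measured_prob
  calc_p <- ifelse(calc_measured,
                   stats::rlnorm(npat, log(3), 0.5), NA_real_)

  # nodule-level: cytology class, then malignancy, then descriptors
  cyt <- .sample_cat(n, spec$cytology_class_probs)
  p_mal_given <- spec$malignancy_prob_given_class[cyt]
  malignant <- stats::runif(n) < p_mal_given
  cond <- conditional_feature_probs(spec)
  feat <- list()
  for (f in names(spec$us_feature_prevalences)) {
    x <- character(n)
    if (any(malignant)) x[malignant] <- .sample_cat(sum(malignant),
                                                    cond$malignant[[f]])
    if (any(!malignant)) x[!malignant] <- .sample_cat(sum(!malignant),
                                                      cond$benign[[f]])
    feat[[f]] <- x
  }

  d_us <- pmin(pmax(stats::rlnorm(n, spec$diameter_log_mean,
                                  spec$diameter_log_sd),
                    spec$diameter_min_mm), spec$diameter_max_mm)
  d_hist <- d_us * spec$histology_shrinkage_scale *
    exp(stats::rnorm(n, 0, spec$histology_diameter_noise_sd))
  d_hist[stats::runif(n) < spec$histology_diameter_missing_prob] <- NA_real_

  diagnosis <- ifelse(
    malignant,
    .sample_cat(n, c(papillary_cancer = 0.75, follicular_cancer = 0.23,
                     medullary_cancer = 0.02)),
    .sample_cat(n, c(goiter = 0.42, adenoma = 0.33, thyroiditis = 0.13,
                     goiter_and_thyroiditis = 0.1, cystic = 0.02))
  )

  cohort <- data.frame(
    nodule_id = sprintf("N%04d", seq_len(n)),
    patient_id = sprintf("P%03d", pat_of),
    composition = feat$composition,
    echogenicity = feat$echogenicity,
    shape = feat$shape,
    margins = feat$margins,
    echogenic_foci = feat$echogenic_foci,
    vascular_pattern = feat$vascular_pattern,
    major_diameter_mm = round(d_us, 1),
    favoring_fna = join_token_set(fav_p[pat_of]),
    against_fna = join_token_set(agn_p[pat_of]),
    exclusions = join_token_set(exc_p[pat_of]),
    family_history_thyroid_cancer = famhist_p[pat_of],
    personal_history_thyroid_cancer = pershist_p[pat_of],
    pathologic_adenopathy = aden_p[pat_of],
    tsh_mUI_per_L = round(tsh_p[pat_of], 2),
    calcitonin_pg_per_mL = round(calc_p[pat_of], 1),
    tpo_ab_elevated = tpo_p[pat_of],
    on_levothyroxine = lt4_p[pat_of],
    cytology = cyt,
    diagnosis_label = diagnosis,
    malignant = malignant,
    histologic_diameter_mm = round(d_hist, 1),
    stringsAsFactors = FALSE
  )
  cohort
}
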