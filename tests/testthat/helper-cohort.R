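# A minimal hand-built cohort row; override any field through ...
toy_nodule <- function(nodule_id = "N1", patient_id = "P1",
                       composition = "solid", echogenicity = "isoechoic",
                       shape = "oval_or_round", margins = "smooth_or_regular",
                       echogenic_foci = "none",
                       vascular_pattern = "peripheral_or_low",
                       major_diameter_mm = 14,
                       favoring_fna = "", against_fna = "", exclusions = "",
                       family_history_thyroid_cancer = FALSE,
                       personal_history_thyroid_cancer = FALSE,
                       pathologic_adenopathy = FALSE,
                       tsh_mUI_per_L = 1.9, calcitonin_pg_per_mL = NA_real_,
                       tpo_ab_elevated = FALSE, on_levothyroxine = FALSE,
                       cytology = "TIR2", diagnosis_label = "goiter",
                       malignant = FALSE,
                       histologic_diameter_mm = NA_real_) {
  data.frame(nodule_id, patient_id, composition, echogenicity, shape, margins,
             echogenic_foci, vascular_pattern, major_diameter_mm, favoring_fna,
             against_fna, exclusions, family_history_thyroid_cancer,
             personal_history_thyroid_cancer, pathologic_adenopathy,
             tsh_mUI_per_L, calcitonin_pg_per_mL, tpo_ab_elevated,
             on_levothyroxine, cytology, diagnosis_label, malignant,
             histologic_diameter_mm, stringsAsFactors = FALSE)
}

toy_cohort <- function(...) {
  rows <- list(...)
  out <- do.call(rbind, rows)
  out$nodule_id <- sprintf("N%03d", seq_len(nrow(out)))
  out
}

# cohort of random in-vocabulary ultrasound configurations
random_us_cohort <- function(n, seed = 99) {
  set.seed(seed)
  voc <- nodule_vocab()
  base <- toy_nodule()[rep(1, n), ]
  base$nodule_id <- sprintf("N%05d", seq_len(n))
  base$composition <- sample(voc$composition, n, replace = TRUE)
  base$echogenicity <- sample(voc$echogenicity, n, replace = TRUE)
  base$shape <- sample(voc$shape, n, replace = TRUE)
  base$margins <- sample(voc$margins, n, replace = TRUE)
  base$echogenic_foci <- sample(voc$echogenic_foci, n, replace = TRUE)
  base$major_diameter_mm <- round(runif(n, 3, 60), 1)
  rownames(base) <- NULL
  base
}

# full Cartesian grid of the five scored descriptors (single-focus sets)
us_feature_grid <- function() {
  voc <- nodule_vocab()
  expand.grid(composition = voc$composition,
              echogenicity = voc$echogenicity,
              shape = voc$shape,
              margins = voc$margins,
              echogenic_foci = voc$echogenic_foci,
              stringsAsFactors = FALSE)
}
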