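#' Controlled vocabularies for nodule records
#'
#' Returns the closed vocabularies used throughout the package: the six
#' ultrasound descriptors (composition, echogenicity, shape, margins,
#' echogenic foci, vascular pattern), the clinical factor sets consumed by
#' the TNAPP engine (factors favoring biopsy, factors against biopsy, and
#' applicability exclusions), and the two cytology reporting systems
#' (SIAPeC-IAP 2014 and Bethesda 2017).
#'
#' Echogenic foci is a *set-valued* descriptor because TI-RADS sums points
#' over all foci present; the token `"none"` may not be combined with any
#' other focus token.
#'
#' @return A named list of character vectors, one per vocabulary.
#' @export
#' @examples
#' nodule_vocab()$composition
nodule_vocab <- function() {
  list(
    composition = c("purely_cystic", "spongiform", "mixed_cystic_solid", "solid"),
    echogenicity = c("anechoic", "hyperechoic", "isoechoic", "hypoechoic",
                     "very_hypoechoic"),
    shape = c("oval_or_round", "taller_than_wide"),
    margins = c("smooth_or_regular", "ill_defined", "irregular_protrusion",
                "spiculated_sharp_angles"),
    echogenic_foci = c("none", "difficult_to_characterize", "macrocalcification",
                       "peripheral_calcification", "microcalcification"),
    vascular_pattern = c("peripheral_or_low", "intranodular"),
    favoring_fna = c("hard_or_fixed_consistency", "head_neck_irradiation_history",
                     "compressive_symptoms", "documented_sudden_enlargement",
                     "cancer_rule_out_protocol",
                     "planned_thyroid_or_parathyroid_surgery"),
    against_fna = c("low_tsh_untreated", "limited_life_expectancy_or_comorbidity",
                    "prior_lobectomy_vocal_cord_paralysis", "pregnancy",
                    "hyperfunctioning_autonomous_nodule",
                    "prior_benign_cytology_same_nodule"),
    exclusions = c("prior_thyroid_cancer", "hereditary_syndrome",
                   "pet_positive_nodule", "elevated_calcitonin",
                   "suspicious_regional_adenopathy"),
    siapec = c("TIR1", "TIR2", "TIR3A", "TIR3B", "TIR4", "TIR5"),
    bethesda = c("I", "II", "III", "IV", "V", "VI")
  )
}

# SIAPeC-IAP 2014 <-> Bethesda 2017 pairing (bijective by construction)
.cytology_pairs <- data.frame(
  siapec = c("TIR1", "TIR2", "TIR3A", "TIR3B", "TIR4", "TIR5"),
  bethesda = c("I", "II", "III", "IV", "V", "VI"),
  stringsAsFactors = FALSE
)

#' Map a cytology label to its paired class in both reporting systems
#'
#' Accepts a label from either the Italian SIAPeC-IAP 2014 system
#' (`TIR1`..`TIR5`, with the indeterminate class split into `TIR3A`/`TIR3B`)
#' or the Bethesda 2017 system (Roman numerals `I`..`VI`) and returns the
#' paired class in both systems. Input is whitespace- and case-tolerant
#' (`"TIR 3A"`, `"tir3a"` and `"III"` all resolve to the same class).
#'
#' @param label Character vector of class labels in either system.
#' @return A data frame with columns `siapec` and `bethesda`, one row per
#'   input label.
#' @export
#' @examples
#' map_cytology("TIR 3A")    # pairs with Bethesda III
#' map_cytology(c("II", "VI"))
map_cytology <- function(label) {
  stopifnot(is.character(label), length(label) >= 1L)
  norm <- toupper(gsub("[[:space:]]+", "", label))
  i <- match(norm, .cytology_pairs$siapec)
  j <- match(norm, .cytology_pairs$bethesda)
  idx <- ifelse(is.na(i), j, i)
  if (anyNA(idx)) {
    bad <- unique(label[is.na(idx)])
    stop("unknown cytology label(s): ", paste(shQuote(bad), collapse = ", "),
         call. = FALSE)
  }
  .cytology_pairs[idx, , drop = FALSE]
}

#' Does a cytology class indicate thyroid surgery?
#'
#' Surgery is indicated for indeterminate-high, suspicious and malignant
#' classes: SIAPeC TIR3B, TIR4 and TIR5 (Bethesda IV, V, VI). Benign and
#' indeterminate-low classes (TIR2, TIR3A; Bethesda II, III) do not indicate
#' surgery. The non-diagnostic class (TIR1 / Bethesda I) is neither positive
#' nor negative and is returned as `NA`; performance analyses drop it.
#'
#' @param cytology Character vector of labels in either reporting system.
#' @return Logical vector: `TRUE` (surgery indicated), `FALSE`, or `NA`
#'   for non-diagnostic cytology.
#' @export
#' @examples
#' cytology_indicates_surgery(c("TIR5", "TIR3A", "TIR1"))
cytology_indicates_surgery <- function(cytology) {
  cls <- map_cytology(cytology)$siapec
  out <- cls %in% c("TIR3B", "TIR4", "TIR5")
  out[cls == "TIR1"] <- NA
  out
}

# --- set-valued fields -------------------------------------------------------

#' Split a semicolon-joined token set into a character vector
#'
#' Cohort files encode set-valued fields (echogenic foci, clinical factor
#' sets) as semicolon-joined tokens; an empty string is the empty set.
#'
#' @param x Character vector of semicolon-joined sets.
#' @return List of character vectors.
#' @export
parse_token_set <- function(x) {
  x[is.na(x)] <- ""
  lapply(strsplit(trimws(x), ";", fixed = TRUE),
         function(t) trimws(t[nzchar(trimws(t))]))
}

#' @rdname parse_token_set
#' @param sets List of character vectors.
#' @export
join_token_set <- function(sets) {
  vapply(sets, paste, character(1), collapse = ";")
}

# Columns of the canonical cohort table, in order. Set-valued columns are
# semicolon-joined; missing numerics are empty cells.
.cohort_columns <- c(
  "nodule_id", "patient_id",
  "composition", "echogenicity", "shape", "margins", "echogenic_foci",
  "vascular_pattern", "major_diameter_mm",
  "favoring_fna", "against_fna", "exclusions",
  "family_history_thyroid_cancer", "personal_history_thyroid_cancer",
  "pathologic_adenopathy",
  "tsh_mUI_per_L", "calcitonin_pg_per_mL", "tpo_ab_elevated", "on_levothyroxine",
  "cytology", "diagnosis_label", "malignant", "histologic_diameter_mm"
)

#' Column names of the canonical cohort table
#' @return Character vector of column names.
#' @export
cohort_columns <- function() .cohort_columns

.check_tokens <- function(values, vocab, field) {
  bad <- setdiff(unique(unlist(values)), vocab)
  if (length(bad)) {
    sprintf("%s: out-of-vocabulary token(s) %s", field,
            paste(shQuote(bad), collapse = ", "))
  } else character(0)
}

#' Validate a cohort table against the controlled vocabularies
#'
#' Checks column presence, closed vocabularies for every categorical field,
#' the echogenic-foci exclusivity rule (`"none"` combines with nothing),
#' positive diameters, nonnegative labs, and unique nodule identifiers.
#'
#' @param cohort A data frame in the canonical cohort schema
#'   (see [cohort_columns()]).
#' @return A character vector of error messages; empty when valid. Each
#'   row-level message carries the offending row number.
#' @export
validate_cohort <- function(cohort) {
  errs <- character(0)
  missing_cols <- setdiff(.cohort_columns, names(cohort))
  if (length(missing_cols)) {
    return(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(cohort) == 0L) return("cohort is empty")
  voc <- nodule_vocab()

  row_err <- function(ok, msg) {
    if (any(!ok)) sprintf("row %d: %s", which(!ok), msg) else character(0)
  }

  for (f in c("composition", "echogenicity", "shape", "margins",
              "vascular_pattern")) {
    errs <- c(errs, row_err(cohort[[f]] %in% voc[[f]],
                            sprintf("invalid %s token", f)))
  }
  foci <- parse_token_set(cohort$echogenic_foci)
  foci_ok <- vapply(foci, function(t) {
    length(t) >= 1L && all(t %in% voc$echogenic_foci) &&
      !("none" %in% t && length(t) > 1L)
  }, logical(1))
  errs <- c(errs, row_err(foci_ok, "invalid echogenic_foci set"))

  for (f in c("favoring_fna", "against_fna", "exclusions")) {
    sets <- parse_token_set(cohort[[f]])
    ok <- vapply(sets, function(t) all(t %in% voc[[f]]), logical(1))
    errs <- c(errs, row_err(ok, sprintf("invalid %s token", f)))
  }

  cyt <- cohort$cytology
  has_cyt <- !is.na(cyt) & nzchar(cyt)
  if (any(has_cyt)) {
    norm <- toupper(gsub("[[:space:]]+", "", cyt[has_cyt]))
    ok_cyt <- rep(TRUE, nrow(cohort))
    ok_cyt[has_cyt] <- norm %in% c(.cytology_pairs$siapec, .cytology_pairs$bethesda)
    errs <- c(errs, row_err(ok_cyt, "unrecognized cytology class"))
  }

  errs <- c(errs, row_err(!is.na(cohort$major_diameter_mm) &
                            cohort$major_diameter_mm > 0,
                          "major_diameter_mm must be positive"))
  for (f in c("tsh_mUI_per_L", "calcitonin_pg_per_mL", "histologic_diameter_mm")) {
    ok <- is.na(cohort[[f]]) | cohort[[f]] >= 0
    errs <- c(errs, row_err(ok, sprintf("%s must be nonnegative", f)))
  }
  if (anyDuplicated(cohort$nodule_id)) {
    errs <- c(errs, sprintf("duplicated nodule_id: %s",
                            paste(unique(cohort$nodule_id[duplicated(cohort$nodule_id)]),
                                  collapse = ", ")))
  }
  errs
}

#' Stop on an invalid cohort
#' @inheritParams validate_cohort
#' @return The cohort, invisibly, when valid.
#' @export
assert_cohort <- function(cohort) {
  errs <- validate_cohort(cohort)
  if (length(errs)) {
    stop("invalid cohort:\n", paste(" -", utils::head(errs, 20), collapse = "\n"),
         if (length(errs) > 20) sprintf("\n (+%d more)", length(errs) - 20),
         call. = FALSE)
  }
  invisible(cohort)
}
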