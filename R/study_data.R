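#' Printed summary tables of the retrospective validation series
#'
#' The package's defaults emulate a single-centre retrospective series of
#' 188 surgically treated thyroid nodules in 112 patients, for which the
#' published report prints per-algorithm 2x2 tables against histology, a
#' cytology-vs-histology 2x2 table, per-class cytology counts with their
#' malignant outcomes, and two pairwise concordance analyses. Those printed
#' summaries are reproduced here as data so the worked examples — metric
#' recomputation, the surgery-indication rule on the class counts, and the
#' concordance arithmetic — can be run without the (undeposited) per-nodule
#' registry.
#'
#' `study_confusion_tables()` returns the four printed 2x2 tables as
#' [confusion_table()] objects: `cytology` (surgery-indicating cytology vs
#' malignant histology, 176 nodules after excluding the 12 non-diagnostic),
#' and the `aace`, `tirads` and `tnapp` triage decisions vs malignant
#' histology (188 nodules each). Note the published TI-RADS table prints a
#' specificity of 70.5% that is inconsistent with its own counts
#' (62/109 = 56.9%) and equals its NPV; [metrics()] computes from the counts.
#'
#' @return For `study_confusion_tables()`, a named list of
#'   [confusion_table()] objects.
#' @export
#' @examples
#' metrics(study_confusion_tables()$tnapp)
study_confusion_tables <- function() {
  list(
    cytology = confusion_table(tp = 70, fp = 35, fn = 7, tn = 64,
                               n_dropped = 12L),
    aace = confusion_table(tp = 66, fp = 80, fn = 13, tn = 29),
    tirads = confusion_table(tp = 53, fp = 47, fn = 26, tn = 62),
    tnapp = confusion_table(tp = 65, fp = 79, fn = 14, tn = 30)
  )
}

#' @rdname study_confusion_tables
#' @return For `study_cytology_counts()`, a data frame with one row per
#'   SIAPeC class: `siapec`, `bethesda`, `n` nodules, and `n_malignant` at
#'   histology.
#' @export
study_cytology_counts <- function() {
  data.frame(
    siapec = c("TIR1", "TIR2", "TIR3A", "TIR3B", "TIR4", "TIR5"),
    bethesda = c("I", "II", "III", "IV", "V", "VI"),
    n = c(12L, 47L, 24L, 44L, 19L, 42L),
    n_malignant = c(3L, 0L, 7L, 15L, 12L, 42L),
    stringsAsFactors = FALSE
  )
}

#' @rdname study_confusion_tables
#' @return For `study_concordance_counts()`, a named list per algorithm pair
#'   with the printed pair count, agreement count, and per-arm breakdown of
#'   the first algorithm's recommendation.
#' @export
study_concordance_counts <- function() {
  list(
    aace_vs_tnapp = list(
      n_pairs = 188L, n_agree = 172L,
      arms = data.frame(arm = c("no_fna_followup", "perform_fna"),
                        n = c(42L, 146L),
                        percent_agreement = c(83.3, 93.8),
                        stringsAsFactors = FALSE)
    ),
    tirads_vs_tnapp = list(
      n_pairs = 188L, n_agree = 144L,
      arms = data.frame(arm = c("no_fna_followup", "perform_fna"),
                        n = c(88L, 100L),
                        percent_agreement = c(50, 100),
                        stringsAsFactors = FALSE)
    )
  )
}
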