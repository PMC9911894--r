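#' Default TNAPP engine configuration
#'
#' TNAPP layers patient-level clinical factors and applicability exclusions
#' on an AACE/ACE/AME ultrasound risk base and emits a four-valued action:
#' `excluded`, `no_fna_followup`, `fna_suggested`, or `fna_recommended`.
#'
#' * `calcitonin_threshold_pg_ml`: serum calcitonin above this value counts
#'   as the "elevated calcitonin" exclusion (default 10 pg/mL, so even a
#'   mild elevation such as 14.5 pg/mL renders the tool inapplicable).
#' * `independent_size_mm`: a major diameter above this value is by itself
#'   sufficient for at least a *suggested* biopsy, whatever the risk class
#'   (default 20 mm).
#' * `small_nodule_mm`: below this diameter, with no adenopathy and no
#'   thyroid-cancer history, the decision is always follow-up (default 5 mm).
#' * `favoring_beats_against`: when a patient carries factors both for and
#'   against biopsy, the favoring factors win (default `TRUE`).
#' * `us_only`: ignore the clinical-modifier layer and decide from
#'   ultrasound and size alone (default `FALSE`).
#'
#' @return A list of the tunables above plus the embedded [aace_config()].
#' @export
tnapp_config <- function() {
  list(
    calcitonin_threshold_pg_ml = 10,
    independent_size_mm = 20,
    small_nodule_mm = 5,
    favoring_beats_against = TRUE,
    us_only = FALSE,
    aace = aace_config()
  )
}

#' Is TNAPP applicable to this patient?
#'
#' TNAPP is unsuitable when any exclusion criterion is present: prior
#' thyroid cancer, a hereditary predisposing syndrome (Gardner, Cowden,
#' familial adenomatous polyposis, Werner, Carney complex), a PET-positive
#' nodule, elevated calcitonin, or suspicious regional adenopathy.
#'
#' @param exclusions Character vector of semicolon-joined exclusion tokens
#'   (or a list of character vectors); see `nodule_vocab()$exclusions`.
#' @param calcitonin_pg_per_mL Numeric, `NA` when unmeasured. A missing
#'   value is treated as non-elevated.
#' @param config See [tnapp_config()].
#' @return A data frame with columns `applicable` (logical) and `reasons`
#'   (semicolon-joined firing exclusions).
#' @export
#' @examples
#' tnapp_applicability("pet_positive_nodule", NA)
tnapp_applicability <- function(exclusions, calcitonin_pg_per_mL = NA_real_,
                                config = tnapp_config()) {
  excl <- if (is.list(exclusions)) exclusions else parse_token_set(exclusions)
  n <- length(excl)
  calc <- rep_len(calcitonin_pg_per_mL, n)
  elevated <- !is.na(calc) & calc > config$calcitonin_threshold_pg_ml
  reasons <- mapply(function(t, e) {
    unique(c(t, if (e) "elevated_calcitonin"))
  }, excl, elevated, SIMPLIFY = FALSE)
  data.frame(applicable = lengths(reasons) == 0L,
             reasons = join_token_set(reasons), stringsAsFactors = FALSE)
}

#' TNAPP decision for a cohort of nodules
#'
#' Rules are evaluated in a fixed order and every fired rule is recorded in
#' an audit trail:
#'
#' 1. **Exclusions** — any applicability exclusion yields `excluded`.
#' 2. **Ultrasound base** — the AACE/ACE/AME class of the nodule.
#' 3. **Ultrasound/size indication** — a high-risk (US3) nodule of at least
#'    5 mm yields `fna_recommended`; size-based clauses (US2/US3 above
#'    10 mm, US1 above 20 mm, any nodule above 20 mm, thyroid-cancer
#'    history above 5 mm, adenopathy from 5 mm) yield `fna_suggested`.
#' 4. **Clinical modifiers** (skipped in `us_only` mode) — any factor
#'    favoring biopsy upgrades the action one step (`no_fna_followup` to
#'    `fna_suggested`, `fna_suggested` to `fna_recommended`); any factor
#'    against biopsy, in the absence of favoring factors, downgrades
#'    `fna_suggested` to `no_fna_followup`. A `fna_recommended` driven by
#'    high-risk ultrasound is never downgraded.
#' 5. **Small-nodule override** — below 5 mm, with no adenopathy and no
#'    thyroid-cancer history, the decision is `no_fna_followup`.
#'
#' @param cohort Data frame in the canonical cohort schema.
#' @param config See [tnapp_config()]; set `config$us_only = TRUE` for a
#'   decision from ultrasound and size alone.
#' @return Data frame: `nodule_id`, `base_us_class`, `action`, and
#'   `fired_rules` (pipe-joined ordered rule identifiers).
#' @export
tnapp_assess <- function(cohort, config = tnapp_config()) {
  missing_us <- setdiff(c("composition", "echogenicity", "shape", "margins",
                          "echogenic_foci", "major_diameter_mm"),
                        names(cohort))
  if (length(missing_us)) {
    stop("incomplete record: missing field(s) ",
         paste(missing_us, collapse = ", "), call. = FALSE)
  }
  if (anyNA(cohort$major_diameter_mm) || any(cohort$major_diameter_mm <= 0)) {
    stop("incomplete record: major_diameter_mm must be present and positive",
         call. = FALSE)
  }

  n <- nrow(cohort)
  app <- tnapp_applicability(cohort$exclusions, cohort$calcitonin_pg_per_mL,
                             config = config)
  base <- aace_class(cohort$composition, cohort$echogenicity, cohort$shape,
                     cohort$margins, cohort$echogenic_foci,
                     config = config$aace)$us_class
  d <- cohort$major_diameter_mm
  hist <- isTRUE_vec(cohort$family_history_thyroid_cancer) |
    isTRUE_vec(cohort$personal_history_thyroid_cancer)
  aden <- isTRUE_vec(cohort$pathologic_adenopathy)
  favoring <- parse_token_set(cohort$favoring_fna)
  against <- parse_token_set(cohort$against_fna)
  thr <- config$aace$fna

  action <- character(n)
  trace <- vector("list", n)
  rank <- c(no_fna_followup = 0L, fna_suggested = 1L, fna_recommended = 2L)

  for (i in seq_len(n)) {
    fired <- character(0)
    if (!app$applicable[i]) {
      action[i] <- "excluded"
      trace[[i]] <- paste0("exclusion:", strsplit(app$reasons[i], ";")[[1]])
      next
    }
    fired <- c(fired, paste0("us_base:", base[i]))
    act <- "no_fna_followup"

    if (base[i] == "US3" && d[i] >= thr[["us3_min"]]) {
      act <- "fna_recommended"
      fired <- c(fired, "us3_high_risk_size")
    } else {
      if (base[i] %in% c("US2", "US3") &&
          (if (isTRUE(config$aace$us23_strict)) d[i] > thr[["us23_over"]]
           else d[i] >= thr[["us23_over"]])) {
        act <- "fna_suggested"; fired <- c(fired, "us2_us3_over_10mm")
      }
      if (base[i] == "US1" && d[i] > thr[["us1_over"]]) {
        act <- "fna_suggested"; fired <- c(fired, "us1_over_20mm")
      }
      if (d[i] > config$independent_size_mm && act == "no_fna_followup") {
        act <- "fna_suggested"; fired <- c(fired, "size_over_20mm_independent")
      } else if (d[i] > config$independent_size_mm) {
        fired <- c(fired, "size_over_20mm_independent")
      }
      if (hist[i] && d[i] > thr[["history_over"]] && rank[act] < 1L) {
        act <- "fna_suggested"; fired <- c(fired, "thyroid_cancer_history")
      }
      if (aden[i] && d[i] >= thr[["adenopathy_min"]] && rank[act] < 1L) {
        act <- "fna_suggested"; fired <- c(fired, "pathologic_adenopathy")
      }
    }

    if (!isTRUE(config$us_only)) {
      has_fav <- length(favoring[[i]]) > 0L
      has_agn <- length(against[[i]]) > 0L
      if (has_fav && has_agn && !isTRUE(config$favoring_beats_against)) {
        has_fav <- FALSE
      }
      if (has_fav) {
        if (act == "fna_suggested") {
          act <- "fna_recommended"
          fired <- c(fired, paste0("favoring_upgrade:", favoring[[i]][1]))
        } else if (act == "no_fna_followup") {
          act <- "fna_suggested"
          fired <- c(fired, paste0("favoring_upgrade:", favoring[[i]][1]))
        }
      } else if (has_agn && act == "fna_suggested") {
        act <- "no_fna_followup"
        fired <- c(fired, paste0("against_downgrade:", against[[i]][1]))
      }
    }

    if (d[i] < config$small_nodule_mm && !aden[i] && !hist[i] &&
        act != "no_fna_followup") {
      act <- "no_fna_followup"
      fired <- c(fired, "small_nodule_override")
    }

    action[i] <- act
    trace[[i]] <- fired
  }

  data.frame(nodule_id = cohort$nodule_id, base_us_class = base,
             action = action,
             fired_rules = vapply(trace, paste, character(1), collapse = "|"),
             stringsAsFactors = FALSE)
}

#' Collapse a four-valued TNAPP action to the binary perform/avoid decision
#'
#' `fna_suggested` and `fna_recommended` both count as "perform FNA";
#' `excluded` becomes `NA` (the tool issues no recommendation).
#'
#' @param action Character vector of TNAPP actions.
#' @return Logical vector: perform FNA (`TRUE`/`FALSE`/`NA`).
#' @export
tnapp_binary <- function(action) {
  out <- action %in% c("fna_suggested", "fna_recommended")
  out[action == "excluded"] <- NA
  out
}
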