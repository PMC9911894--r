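#' Default AACE/ACE/AME classification configuration
#'
#' The three-tier ultrasound risk system assigns US3 (high risk) when any
#' high-risk sign is present, US1 (low risk) to the benign morphologies
#' (purely cystic nodules, isoechoic spongiform nodules, mixed cystic/solid
#' nodules without suspicious signs), and US2 (intermediate) to everything
#' else. Intranodular vascularity and macro/peripheral/indeterminate
#' calcifications do not by themselves promote a nodule to US3.
#'
#' Biopsy thresholds (mm): high-risk (US3) nodules from 5 mm, any US2/US3
#' nodule above 10 mm, low-risk (US1) nodules above 20 mm; nodules above
#' 5 mm with pathologic cervical adenopathy (>= 5) or a personal/family
#' history of thyroid cancer (> 5) regardless of class. The `us23_strict`
#' flag controls whether "above 10 mm" is read strictly (default, `d > 10`)
#' or inclusively (`d >= 10`).
#'
#' @return A list: `high_risk` (the trigger features), `fna` thresholds, and
#'   `us23_strict`.
#' @export
aace_config <- function() {
  list(
    high_risk = list(
      echogenicity = "very_hypoechoic",
      margins = c("spiculated_sharp_angles", "irregular_protrusion"),
      shape = "taller_than_wide",
      echogenic_foci = "microcalcification"
    ),
    fna = c(us3_min = 5, adenopathy_min = 5, history_over = 5,
            us23_over = 10, us1_over = 20),
    us23_strict = TRUE
  )
}

#' AACE/ACE/AME ultrasound risk class
#'
#' @inheritParams tirads_points
#' @param config See [aace_config()].
#' @return A data frame with columns `us_class` (`US1`/`US2`/`US3`) and
#'   `triggering_features` (semicolon-joined high-risk features; empty unless
#'   US3).
#' @export
#' @examples
#' aace_class("purely_cystic", "anechoic", "oval_or_round",
#'            "smooth_or_regular", "none")$us_class  # US1
aace_class <- function(composition, echogenicity, shape, margins,
                       echogenic_foci, config = aace_config()) {
  hr <- config$high_risk
  foci <- if (is.list(echogenic_foci)) echogenic_foci else parse_token_set(echogenic_foci)
  n <- length(composition)
  triggers <- vector("list", n)
  for (i in seq_len(n)) {
    t <- character(0)
    if (echogenicity[i] %in% hr$echogenicity) t <- c(t, echogenicity[i])
    if (margins[i] %in% hr$margins) t <- c(t, margins[i])
    if (shape[i] %in% hr$shape) t <- c(t, shape[i])
    t <- c(t, intersect(foci[[i]], hr$echogenic_foci))
    triggers[[i]] <- t
  }
  high <- lengths(triggers) > 0L
  low <- !high & (composition == "purely_cystic" |
                    (composition == "spongiform" & echogenicity == "isoechoic") |
                    composition == "mixed_cystic_solid")
  data.frame(
    us_class = ifelse(high, "US3", ifelse(low, "US1", "US2")),
    triggering_features = join_token_set(triggers),
    stringsAsFactors = FALSE
  )
}

#' AACE/ACE/AME biopsy indication
#'
#' @param us_class Character vector `US1`/`US2`/`US3`.
#' @param major_diameter_mm Positive numeric, millimetres.
#' @param family_or_personal_history Logical: personal or family history of
#'   thyroid cancer.
#' @param pathologic_adenopathy Logical: pathologic cervical lymph nodes.
#' @param config See [aace_config()].
#' @return Character vector: `"fna_recommended"` or `"no_fna"`.
#' @export
aace_fna_indication <- function(us_class, major_diameter_mm,
                                family_or_personal_history = FALSE,
                                pathologic_adenopathy = FALSE,
                                config = aace_config()) {
  stopifnot(all(us_class %in% c("US1", "US2", "US3")),
            all(major_diameter_mm > 0))
  d <- major_diameter_mm
  thr <- config$fna
  us23 <- us_class %in% c("US2", "US3")
  us23_fire <- if (isTRUE(config$us23_strict)) d > thr[["us23_over"]] else
    d >= thr[["us23_over"]]
  fire <- (us_class == "US3" & d >= thr[["us3_min"]]) |
    (pathologic_adenopathy & d >= thr[["adenopathy_min"]]) |
    (family_or_personal_history & d > thr[["history_over"]]) |
    (us23 & us23_fire) |
    (us_class == "US1" & d > thr[["us1_over"]])
  ifelse(fire, "fna_recommended", "no_fna")
}

#' Classify a whole cohort with AACE/ACE/AME
#'
#' @param cohort Data frame in the canonical cohort schema.
#' @param config See [aace_config()].
#' @return Data frame: `nodule_id`, `us_class`, `triggering_features`,
#'   `action`.
#' @export
aace_assess <- function(cohort, config = aace_config()) {
  cls <- aace_class(cohort$composition, cohort$echogenicity, cohort$shape,
                    cohort$margins, cohort$echogenic_foci, config = config)
  hist <- isTRUE_vec(cohort$family_history_thyroid_cancer) |
    isTRUE_vec(cohort$personal_history_thyroid_cancer)
  aden <- isTRUE_vec(cohort$pathologic_adenopathy)
  act <- aace_fna_indication(cls$us_class, cohort$major_diameter_mm,
                             family_or_personal_history = hist,
                             pathologic_adenopathy = aden, config = config)
  cbind(data.frame(nodule_id = cohort$nodule_id), cls,
        data.frame(action = act, stringsAsFactors = FALSE))
}

# missing logicals are treated as FALSE (non-actionable)
isTRUE_vec <- function(x) !is.na(x) & x
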