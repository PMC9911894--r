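#' Default ACR TI-RADS configuration
#'
#' The additive point table over the five scored ultrasound descriptors
#' (vascular pattern carries no points), the point-to-category bins, and the
#' size thresholds at which each category indicates biopsy. Mixed
#' cystic/solid nodules are scored on the echogenicity of their solid
#' component, so the echogenicity column applies unchanged. Indeterminate
#' ("difficult to characterize") foci score 0, like comet-tail artifacts.
#'
#' The whole table is configuration: pass an edited copy (or a YAML file via
#' [read_triage_config()]) to score under an alternative lexicon version.
#'
#' @return A nested list with elements `points` (per-feature integer tables),
#'   `category_breaks` (lower bound of each category) and `fna_min_diameter_mm`
#'   (per-category biopsy threshold in mm, `Inf` = never).
#' @export
tirads_config <- function() {
  list(
    points = list(
      composition = c(purely_cystic = 0, spongiform = 0,
                      mixed_cystic_solid = 1, solid = 2),
      echogenicity = c(anechoic = 0, hyperechoic = 1, isoechoic = 1,
                       hypoechoic = 2, very_hypoechoic = 3),
      shape = c(oval_or_round = 0, taller_than_wide = 3),
      margins = c(smooth_or_regular = 0, ill_defined = 0,
                  irregular_protrusion = 2, spiculated_sharp_angles = 3),
      echogenic_foci = c(none = 0, difficult_to_characterize = 0,
                         macrocalcification = 1, peripheral_calcification = 2,
                         microcalcification = 3)
    ),
    # points >= break -> category; evaluated from the top
    category_breaks = c(TR1 = 0, TR2 = 2, TR3 = 3, TR4 = 4, TR5 = 7),
    fna_min_diameter_mm = c(TR1 = Inf, TR2 = Inf, TR3 = 25, TR4 = 15, TR5 = 10)
  )
}

#' ACR TI-RADS point score with per-feature breakdown
#'
#' Sums the point contributions of composition, echogenicity, shape,
#' margins, and echogenic foci. Foci points are summed over *all* foci
#' present, so a nodule with both macro- and microcalcifications scores
#' 1 + 3 on that descriptor.
#'
#' @param composition,echogenicity,shape,margins Character vectors drawn
#'   from the vocabularies of [nodule_vocab()].
#' @param echogenic_foci Character vector of semicolon-joined focus sets, or
#'   a list of character vectors.
#' @param config Point table, default [tirads_config()].
#' @return A data frame with one row per nodule: the five per-feature point
#'   columns and their sum in `points`.
#' @export
#' @examples
#' tirads_points("solid", "isoechoic", "oval_or_round", "smooth_or_regular",
#'               "none")$points  # 3
tirads_points <- function(composition, echogenicity, shape, margins,
                          echogenic_foci, config = tirads_config()) {
  pts <- config$points
  lookup <- function(tab, x, field) {
    p <- tab[x]
    if (anyNA(p)) {
      stop(sprintf("%s: unknown token(s) %s", field,
                   paste(shQuote(unique(x[is.na(p)])), collapse = ", ")),
           call. = FALSE)
    }
    unname(p)
  }
  foci <- if (is.list(echogenic_foci)) echogenic_foci else parse_token_set(echogenic_foci)
  foci_pts <- vapply(foci, function(t) {
    if (!length(t)) stop("echogenic_foci must not be empty; use 'none'",
                         call. = FALSE)
    sum(lookup(pts$echogenic_foci, t, "echogenic_foci"))
  }, numeric(1))
  out <- data.frame(
    composition = lookup(pts$composition, composition, "composition"),
    echogenicity = lookup(pts$echogenicity, echogenicity, "echogenicity"),
    shape = lookup(pts$shape, shape, "shape"),
    margins = lookup(pts$margins, margins, "margins"),
    echogenic_foci = foci_pts
  )
  out$points <- rowSums(out)
  out
}

#' Map a TI-RADS point total to its TR category
#'
#' Bins: 0 points TR1, 2 points TR2, 3 points TR3, 4-6 points TR4,
#' 7 or more TR5. A total of exactly 1 point is unreachable from valid
#' descriptor combinations under the default table; it maps to TR1 with a
#' warning so the function stays total.
#'
#' @param points Nonnegative integer vector of point totals.
#' @param config See [tirads_config()].
#' @return Character vector of categories `TR1`..`TR5`.
#' @export
tirads_category <- function(points, config = tirads_config()) {
  if (any(is.na(points)) || any(points < 0)) {
    stop("points must be nonnegative", call. = FALSE)
  }
  br <- config$category_breaks
  if (any(points == 1)) {
    warning("point total of 1 is not produced by any valid descriptor ",
            "combination; mapping to TR1")
  }
  idx <- findInterval(points, br)  # breaks sorted ascending
  names(br)[pmax(idx, 1L)]
}

#' TI-RADS biopsy indication by category and size
#'
#' Biopsy is recommended for TR3 nodules of major diameter >= 25 mm, TR4
#' >= 15 mm, and TR5 >= 10 mm; TR1 and TR2 nodules are never biopsied on
#' imaging grounds.
#'
#' @param category Character vector `TR1`..`TR5`.
#' @param major_diameter_mm Positive numeric vector, millimetres.
#' @param config See [tirads_config()].
#' @return Character vector: `"fna_recommended"` or `"no_fna"`.
#' @export
tirads_fna_indication <- function(category, major_diameter_mm,
                                  config = tirads_config()) {
  thr <- config$fna_min_diameter_mm[category]
  if (anyNA(thr)) stop("unknown TI-RADS category", call. = FALSE)
  stopifnot(all(major_diameter_mm > 0))
  ifelse(major_diameter_mm >= unname(thr), "fna_recommended", "no_fna")
}

#' Score a whole cohort with ACR TI-RADS
#'
#' @param cohort Data frame in the canonical cohort schema.
#' @param config See [tirads_config()].
#' @return A data frame with one row per nodule: `nodule_id`, per-feature
#'   points, `points`, `category`, and `action`.
#' @export
tirads_assess <- function(cohort, config = tirads_config()) {
  bd <- tirads_points(cohort$composition, cohort$echogenicity, cohort$shape,
                      cohort$margins, cohort$echogenic_foci, config = config)
  cat <- tirads_category(bd$points, config = config)
  act <- tirads_fna_indication(cat, cohort$major_diameter_mm, config = config)
  cbind(data.frame(nodule_id = cohort$nodule_id), bd,
        data.frame(category = cat, action = act))
}
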