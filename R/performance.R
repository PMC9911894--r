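#' Construct a 2x2 confusion table of triage decision against malignancy
#'
#' The positive call is "FNA performed / surgery indicated" and the truth is
#' malignant histology (or, when cytology serves as the reference, a
#' surgery-indicating cytology class). Nodules whose truth is missing (e.g.
#' non-diagnostic cytology) are dropped and their number recorded.
#'
#' @param decision Logical vector: positive call per nodule.
#' @param truth Logical vector: malignant per nodule; `NA` drops the nodule.
#' @return An object of class `confusion_table`: list with integer counts
#'   `tp`, `fp`, `fn`, `tn`, plus `n_dropped`.
#' @export
#' @examples
#' build_confusion(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
build_confusion <- function(decision, truth) {
  if (length(decision) != length(truth)) {
    stop("decision and truth have different lengths (",
         length(decision), " vs ", length(truth), ")", call. = FALSE)
  }
  if (length(decision) == 0L) stop("empty input", call. = FALSE)
  keep <- !is.na(truth) & !is.na(decision)
  d <- decision[keep]; t <- truth[keep]
  if (!length(d)) stop("no nodule has a usable reference value", call. = FALSE)
  confusion_table(tp = sum(d & t), fp = sum(d & !t),
                  fn = sum(!d & t), tn = sum(!d & !t),
                  n_dropped = sum(!keep))
}

#' @rdname build_confusion
#' @param tp,fp,fn,tn Nonnegative integer counts.
#' @param n_dropped Nodules excluded for missing reference.
#' @export
confusion_table <- function(tp, fp, fn, tn, n_dropped = 0L) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn),
                 n_dropped = as.integer(n_dropped)),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, byrow = TRUE,
              dimnames = list(c("positive call", "negative call"),
                              c("malignant", "benign")))
  print(m)
  if (x$n_dropped > 0) cat(x$n_dropped, "nodule(s) dropped (missing reference)\n")
  invisible(x)
}

#' Diagnostic accuracy metrics from a 2x2 table
#'
#' Sensitivity, specificity, positive and negative predictive values and
#' overall accuracy, computed exactly from the integer counts. A metric
#' whose denominator is zero is *undefined* and reported as `NA`, never as
#' 0 or 1. Percent renderings are rounded to one decimal; Wilson 95%
#' confidence intervals are attached for logging but carry no rounding
#' guarantee.
#'
#' @param table A [confusion_table()].
#' @return An object of class `performance_metrics`: list with `proportions`
#'   (named numeric, exact), `percent` (one-decimal renderings),
#'   `wilson_ci` (2-column matrix), and the source counts.
#' @export
#' @examples
#' metrics(confusion_table(tp = 65, fp = 79, fn = 14, tn = 30))
metrics <- function(table) {
  stopifnot(inherits(table, "confusion_table"))
  tp <- table$tp; fp <- table$fp; fn <- table$fn; tn <- table$tn
  total <- tp + fp + fn + tn
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  prop <- c(
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    ppv = ratio(tp, tp + fp),
    npv = ratio(tn, tn + fn),
    accuracy = ratio(tp + tn, total)
  )
  dens <- c(tp + fn, tn + fp, tp + fp, tn + fn, total)
  nums <- c(tp, tn, tp, tn, tp + tn)
  ci <- t(mapply(wilson_interval, nums, dens))
  dimnames(ci) <- list(names(prop), c("lower", "upper"))
  structure(list(proportions = prop,
                 percent = round(100 * prop, 1),
                 wilson_ci = ci,
                 counts = table),
            class = "performance_metrics")
}

#' @export
print.performance_metrics <- function(x, ...) {
  p <- x$percent
  lab <- c(sensitivity = "Sensitivity", specificity = "Specificity",
           ppv = "PPV", npv = "NPV", accuracy = "Accuracy")
  for (k in names(p)) {
    cat(sprintf("%-12s %s\n", lab[k],
                if (is.na(p[k])) "undefined (zero denominator)"
                else sprintf("%.1f%%", p[k])))
  }
  invisible(x)
}

#' Wilson score 95% confidence interval for a binomial proportion
#' @param x Successes. @param n Trials.
#' @return Numeric length-2 vector (lower, upper); `NA` when `n` is 0.
#' @keywords internal
wilson_interval <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, centre - half), min(1, centre + half))
}

#' Percent agreement between two triage algorithms
#'
#' Overall percent agreement of two binary perform/avoid-FNA decision
#' vectors, optionally stratified by major-diameter bands
#' (<=10, 11-20, 21-40, >40 mm) and conditioned on each recommendation arm
#' of the first algorithm (agreement among its positive calls and among its
#' negative calls).
#'
#' @param decisions_a,decisions_b Logical vectors, aligned per nodule.
#' @param diameters_mm Optional numeric vector of major diameters for the
#'   stratified analysis.
#' @return An object of class `concordance_report`: `n_pairs`, `n_agree`,
#'   `percent_agreement`, and data frames `strata` and `arms` when
#'   requested/available.
#' @export
#' @examples
#' concordance(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, FALSE, FALSE, FALSE))
concordance <- function(decisions_a, decisions_b, diameters_mm = NULL) {
  if (length(decisions_a) != length(decisions_b)) {
    stop("decision vectors have different lengths", call. = FALSE)
  }
  if (!is.null(diameters_mm) && length(diameters_mm) != length(decisions_a)) {
    stop("diameters_mm length does not match the decisions", call. = FALSE)
  }
  keep <- !is.na(decisions_a) & !is.na(decisions_b)
  a <- decisions_a[keep]; b <- decisions_b[keep]
  n <- length(a)
  if (n == 0L) stop("no comparable pairs", call. = FALSE)
  agree <- a == b

  pct <- function(num, den) if (den > 0) round(100 * num / den, 1) else NA_real_

  strata <- NULL
  if (!is.null(diameters_mm)) {
    d <- diameters_mm[keep]
    band <- cut(d, breaks = c(-Inf, 10, 20, 40, Inf),
                labels = c("<=10", "11-20", "21-40", ">40"))
    strata <- do.call(rbind, lapply(levels(band), function(lv) {
      idx <- band == lv
      data.frame(band = lv, n = sum(idx), n_agree = sum(agree[idx]),
                 percent_agreement = pct(sum(agree[idx]), sum(idx)),
                 stringsAsFactors = FALSE)
    }))
  }

  arms <- do.call(rbind, lapply(c(TRUE, FALSE), function(arm) {
    idx <- a == arm
    data.frame(arm = if (arm) "perform_fna" else "no_fna_followup",
               n = sum(idx), n_agree = sum(agree[idx]),
               percent_agreement = pct(sum(agree[idx]), sum(idx)),
               stringsAsFactors = FALSE)
  }))

  structure(list(n_pairs = n, n_agree = sum(agree),
                 percent_agreement = pct(sum(agree), n),
                 strata = strata, arms = arms,
                 n_dropped = sum(!keep)),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("Agreement: %d of %d (%.1f%%)\n",
              x$n_agree, x$n_pairs, x$percent_agreement))
  if (!is.null(x$strata)) { cat("By diameter band (mm):\n"); print(x$strata) }
  cat("By recommendation arm of algorithm A:\n"); print(x$arms)
  invisible(x)
}

#' Distribution of avoided biopsies across cytology classes
#'
#' Among the nodules an algorithm would *not* biopsy, counts and shares per
#' cytology class — the "avoidable FNA" analysis: a high share of benign
#' (TIR2) cytology among avoided biopsies means the algorithm skips mostly
#' unnecessary procedures.
#'
#' @param decision Logical perform-FNA vector.
#' @param cytology Character vector of cytology labels (either system).
#' @return Data frame with `siapec`, `n`, `percent` (share of all avoided
#'   biopsies, one decimal); zero rows when no biopsy is avoided.
#' @export
avoidable_fna_by_cytology <- function(decision, cytology) {
  if (length(decision) != length(cytology)) {
    stop("decision and cytology have different lengths", call. = FALSE)
  }
  keep <- !is.na(decision) & !decision & !is.na(cytology) & nzchar(cytology)
  if (!any(keep)) {
    return(data.frame(siapec = character(0), n = integer(0),
                      percent = numeric(0), stringsAsFactors = FALSE))
  }
  cls <- factor(map_cytology(cytology[keep])$siapec,
                levels = nodule_vocab()$siapec)
  tab <- table(cls)
  data.frame(siapec = names(tab), n = as.integer(tab),
             percent = round(100 * as.integer(tab) / sum(tab), 1),
             stringsAsFactors = FALSE)
}

#' Malignancies an algorithm would have missed
#'
#' Counts the malignant nodules the algorithm would not have biopsied and,
#' among them, the microcarcinomas — carcinomas with a major diameter of
#' 10 mm or less, taken from the histologic diameter when available and the
#' ultrasound diameter otherwise.
#'
#' @param decision Logical perform-FNA vector.
#' @param malignant Logical histology truth; `NA` drops the nodule.
#' @param histologic_diameter_mm,us_diameter_mm Numeric diameters (mm).
#' @return List: `n_missed`, `n_microcarcinoma`, `fraction_microcarcinoma`
#'   (`NA` when nothing is missed), `percent_microcarcinoma`.
#' @export
missed_malignancy_profile <- function(decision, malignant,
                                      histologic_diameter_mm,
                                      us_diameter_mm) {
  stopifnot(length(decision) == length(malignant),
            length(decision) == length(us_diameter_mm))
  missed <- !is.na(decision) & !decision & !is.na(malignant) & malignant
  n_missed <- sum(missed)
  if (n_missed == 0L) {
    return(list(n_missed = 0L, n_microcarcinoma = 0L,
                fraction_microcarcinoma = NA_real_,
                percent_microcarcinoma = NA_real_))
  }
  d <- ifelse(!is.na(histologic_diameter_mm[missed]),
              histologic_diameter_mm[missed], us_diameter_mm[missed])
  n_micro <- sum(d <= 10, na.rm = TRUE)
  list(n_missed = n_missed, n_microcarcinoma = n_micro,
       fraction_microcarcinoma = n_micro / n_missed,
       percent_microcarcinoma = round(100 * n_micro / n_missed, 1))
}
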