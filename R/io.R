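#' Read and write nodule cohorts
#'
#' The canonical interchange format is a UTF-8, comma-delimited CSV with a
#' header row and one row per nodule; columns are exactly
#' [cohort_columns()], set-valued fields are semicolon-joined and missing
#' numerics are empty cells. A `.json` path reads/writes the equivalent JSON
#' array of records. Loading is all-or-nothing: any vocabulary violation or
#' malformed value aborts with row-numbered messages.
#'
#' @param path File path; format chosen by extension (`.json` vs CSV).
#' @return `read_cohort()`: a validated cohort data frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
    if (!is.data.frame(df)) stop("JSON cohort must be an array of records",
                                 call. = FALSE)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = character(0))
  }
  miss <- setdiff(cohort_columns(), names(df))
  if (length(miss)) {
    stop("cohort file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- df[, cohort_columns()]
  num_cols <- c("major_diameter_mm", "tsh_mUI_per_L", "calcitonin_pg_per_mL",
                "histologic_diameter_mm")
  lgl_cols <- c("family_history_thyroid_cancer", "personal_history_thyroid_cancer",
                "pathologic_adenopathy", "tpo_ab_elevated", "on_levothyroxine",
                "malignant")
  to_num <- function(x) {
    x <- as.character(x); x[!nzchar(trimws(x)) | toupper(x) == "NA"] <- NA
    suppressWarnings(as.numeric(x))
  }
  to_lgl <- function(x) {
    x <- toupper(trimws(as.character(x)))
    out <- rep(NA, length(x))
    out[x %in% c("TRUE", "T", "1", "YES")] <- TRUE
    out[x %in% c("FALSE", "F", "0", "NO")] <- FALSE
    out
  }
  for (cc in num_cols) df[[cc]] <- to_num(df[[cc]])
  for (cc in lgl_cols) df[[cc]] <- to_lgl(df[[cc]])
  assert_cohort(df)
  df
}

#' @rdname read_cohort
#' @param cohort A cohort data frame.
#' @return `write_cohort()`: the path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cohort, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(cohort, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Run one triage algorithm over a cohort
#'
#' @param cohort A cohort data frame (see [cohort_columns()]).
#' @param algorithm `"tirads"`, `"aace"`, or `"tnapp"`.
#' @param config Algorithm configuration; defaults to the matching
#'   `*_config()`.
#' @return A data frame with `nodule_id`, `algorithm`, `risk_label`,
#'   `action`, `perform_fna` (logical; `NA` when the tool is inapplicable)
#'   and `rule_trace`.
#' @export
#' @examples
#' cohort <- generate_cohort(default_cohort_spec(), n_nodules = 20, seed = 3)
#' head(triage_cohort(cohort, "tirads"))
triage_cohort <- function(cohort, algorithm = c("tirads", "aace", "tnapp"),
                          config = NULL) {
  algorithm <- match.arg(algorithm)
  if (algorithm == "tirads") {
    a <- tirads_assess(cohort, config = config %||% tirads_config())
    out <- data.frame(nodule_id = a$nodule_id, algorithm = "tirads",
                      risk_label = a$category, action = a$action,
                      perform_fna = a$action == "fna_recommended",
                      rule_trace = sprintf("points=%d", a$points),
                      stringsAsFactors = FALSE)
  } else if (algorithm == "aace") {
    a <- aace_assess(cohort, config = config %||% aace_config())
    out <- data.frame(nodule_id = a$nodule_id, algorithm = "aace",
                      risk_label = a$us_class, action = a$action,
                      perform_fna = a$action == "fna_recommended",
                      rule_trace = ifelse(nzchar(a$triggering_features),
                                          paste0("high_risk=", a$triggering_features),
                                          ""),
                      stringsAsFactors = FALSE)
  } else {
    a <- tnapp_assess(cohort, config = config %||% tnapp_config())
    out <- data.frame(nodule_id = a$nodule_id, algorithm = "tnapp",
                      risk_label = a$base_us_class, action = a$action,
                      perform_fna = tnapp_binary(a$action),
                      rule_trace = a$fired_rules,
                      stringsAsFactors = FALSE)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a triage configuration from YAML
#'
#' The YAML file may carry any subset of the keys of [tirads_config()],
#' [aace_config()] and [tnapp_config()] under top-level sections `tirads`,
#' `aace`, `tnapp`; unknown keys are rejected. Values are merged over the
#' defaults.
#'
#' @param path YAML file path.
#' @return A list with elements `tirads`, `aace`, `tnapp`.
#' @export
read_triage_config <- function(path) {
  raw <- yaml::read_yaml(path) %||% list()
  defaults <- list(tirads = tirads_config(), aace = aace_config(),
                   tnapp = tnapp_config())
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown)) {
    stop("unknown config section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  merge_in <- function(def, over, where) {
    bad <- setdiff(names(over), names(def))
    if (length(bad)) {
      stop("unknown config key(s) in ", where, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    for (k in names(over)) {
      def[[k]] <- if (is.list(def[[k]]) && is.list(over[[k]])) {
        merge_in(def[[k]], over[[k]], paste0(where, "$", k))
      } else if (is.numeric(def[[k]]) && !is.null(names(def[[k]])) &&
                 is.list(over[[k]])) {
        v <- def[[k]]
        bad2 <- setdiff(names(over[[k]]), names(v))
        if (length(bad2)) stop("unknown config key(s) in ", where, "$", k, ": ",
                               paste(bad2, collapse = ", "), call. = FALSE)
        v[names(over[[k]])] <- unlist(over[[k]])
        v
      } else over[[k]]
    }
    def
  }
  for (s in names(raw)) defaults[[s]] <- merge_in(defaults[[s]], raw[[s]], s)
  # tnapp embeds the aace config; keep them in step unless overridden
  if (!is.null(raw$aace) && is.null(raw$tnapp$aace)) {
    defaults$tnapp$aace <- defaults$aace
  }
  defaults
}

#' Replicate the full triage comparison on a synthetic cohort
#'
#' Chains the whole pipeline: generate (or accept) a cohort, run the three
#' triage algorithms, build each algorithm's 2x2 table against malignant
#' histology, compute accuracy metrics, all pairwise concordances with
#' diameter strata and recommendation arms, the avoidable-biopsy
#' distribution over cytology classes, and the missed-malignancy /
#' microcarcinoma profile. Deterministic given `seed`.
#'
#' @param n_nodules Cohort size (default 188).
#' @param seed Integer seed for the generator.
#' @param spec A `cohort_spec` (default [default_cohort_spec()]).
#' @param cohort Optional pre-built cohort; when given, `n_nodules`, `seed`
#'   and `spec` are ignored for generation.
#' @param us_only Logical; run TNAPP from ultrasound and size alone.
#' @param config Optional list from [read_triage_config()].
#' @return A list: `cohort`, `decisions` (long data frame over the three
#'   algorithms), `metrics` (per algorithm), `concordance` (per pair),
#'   `avoidable_fna` (per algorithm), `missed_malignancy` (per algorithm)
#'   and a reproducibility `manifest`.
#' @export
#' @examples
#' rep <- replicate_study(n_nodules = 60, seed = 11)
#' rep$metrics$tnapp$percent
replicate_study <- function(n_nodules = 188, seed = 1, spec = default_cohort_spec(),
                            cohort = NULL, us_only = FALSE, config = NULL) {
  cfg <- config %||% list(tirads = tirads_config(), aace = aace_config(),
                          tnapp = tnapp_config())
  cfg$tnapp$us_only <- us_only
  if (is.null(cohort)) {
    cohort <- generate_cohort(spec, n_nodules = n_nodules, seed = seed)
  }
  if (nrow(cohort) == 0L) stop("stage simulate: empty cohort", call. = FALSE)
  assert_cohort(cohort)

  algos <- c("tirads", "aace", "tnapp")
  decisions <- lapply(algos, function(a) {
    tryCatch(triage_cohort(cohort, a, config = cfg[[a]]),
             error = function(e) stop("stage triage[", a, "]: ",
                                      conditionMessage(e), call. = FALSE))
  })
  names(decisions) <- algos

  met <- lapply(decisions, function(d) {
    metrics(build_confusion(d$perform_fna, cohort$malignant))
  })
  pairs <- list(aace_vs_tnapp = c("aace", "tnapp"),
                tirads_vs_tnapp = c("tirads", "tnapp"),
                aace_vs_tirads = c("aace", "tirads"))
  conc <- lapply(pairs, function(p) {
    concordance(decisions[[p[1]]]$perform_fna, decisions[[p[2]]]$perform_fna,
                diameters_mm = cohort$major_diameter_mm)
  })
  avoid <- lapply(decisions, function(d) {
    avoidable_fna_by_cytology(d$perform_fna, cohort$cytology)
  })
  missed <- lapply(decisions, function(d) {
    missed_malignancy_profile(d$perform_fna, cohort$malignant,
                              cohort$histologic_diameter_mm,
                              cohort$major_diameter_mm)
  })

  manifest <- list(
    seed = seed, n_nodules = nrow(cohort), us_only = us_only,
    package_version = as.character(utils::packageVersion("noduletriage")),
    config_md5 = config_hash(cfg)
  )
  list(cohort = cohort, decisions = do.call(rbind, unname(decisions)),
       metrics = met, concordance = conc, avoidable_fna = avoid,
       missed_malignancy = missed, manifest = manifest)
}

#' MD5 fingerprint of a configuration object
#' @param cfg Any serializable list.
#' @return Character MD5 hex digest of its canonical JSON form.
#' @export
config_hash <- function(cfg) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(cfg, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}

#' Write a replicate bundle to a directory
#'
#' Emits `decisions.csv`, `metrics.json`, `concordance.json`,
#' `avoidable_fna.json`, `missed_malignancy.json` and `manifest.json`.
#'
#' @param bundle Result of [replicate_study()].
#' @param dir Output directory; created if absent.
#' @return The directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(bundle$decisions, file.path(dir, "decisions.csv"),
                   row.names = FALSE)
  wj <- function(x, f) jsonlite::write_json(
    x, file.path(dir, f), auto_unbox = TRUE, digits = NA, force = TRUE,
    na = "null")
  wj(lapply(bundle$metrics, function(m)
    list(proportions = as.list(m$proportions),
         percent = as.list(m$percent),
         counts = unclass(m$counts))), "metrics.json")
  wj(lapply(bundle$concordance, unclass), "concordance.json")
  wj(bundle$avoidable_fna, "avoidable_fna.json")
  wj(bundle$missed_malignancy, "missed_malignancy.json")
  wj(bundle$manifest, "manifest.json")
  invisible(dir)
}
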