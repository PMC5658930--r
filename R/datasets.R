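# Bundled study data and CSV readers/writers for cohorts and contingencies.

DRUG_VOCAB <- c("Carboplatin", "Paclitaxel", "Topotecan", "Caelyx",
                "Gemcitabine", "Avastin")

# lower-case synonym -> canonical name
DRUG_SYNONYMS <- c(
  "carbo" = "Carboplatin",
  "pac" = "Paclitaxel",
  "topo" = "Topotecan",
  "gem" = "Gemcitabine",
  "pegylated liposomal doxorubicin" = "Caelyx",
  "doxorubicin-hydrochloride in a pegylated liposomal formulation" = "Caelyx",
  "bevacizumab" = "Avastin"
)

#' Controlled drug vocabulary
#'
#' Canonical drug names used by the bundled cohort. Caelyx is the pegylated
#' liposomal formulation of doxorubicin; Avastin (bevacizumab) is carried as
#' metadata only and never scored by the assay.
#'
#' @return Character vector of canonical drug names.
#' @export
drug_vocabulary <- function() DRUG_VOCAB

#' Normalise drug names against the controlled vocabulary
#'
#' Matching is case-insensitive and accepts common abbreviations (Carbo,
#' Pac, Topo, Gem) and synonyms (bevacizumab, pegylated liposomal
#' doxorubicin).
#'
#' @param x Character vector of drug names; `NA`/empty entries pass through
#'   as `NA`.
#' @return Character vector of canonical names.
#' @export
normalise_drug <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & trimws(x) == ""] <- NA_character_
  key <- tolower(trimws(x))
  canon <- setNames(DRUG_VOCAB, tolower(DRUG_VOCAB))
  out <- ifelse(is.na(x), NA_character_,
                ifelse(key %in% names(canon), canon[key],
                       ifelse(key %in% names(DRUG_SYNONYMS),
                              DRUG_SYNONYMS[key], NA_character_)))
  unknown <- !is.na(x) & is.na(out)
  if (any(unknown)) {
    ctr_stop("vocabulary", "validation", "unknown drug name(s): %s",
             paste(unique(x[unknown]), collapse = ", "))
  }
  unname(out)
}

normalise_response <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[x %in% c("non-responder", "non_responder", "nonresponder")] <-
    "non_responder"
  bad <- !x %in% c("responder", "non_responder")
  if (any(bad)) {
    ctr_stop("vocabulary", "validation",
             "unknown response token(s): %s (expected responder/non_responder)",
             paste(unique(x[bad]), collapse = ", "))
  }
  ifelse(x == "responder", "responder", "non_responder")
}

normalise_arm <- function(x) {
  x <- tolower(trimws(as.character(x)))
  ok <- c("mono", "mono_plus_avastin", "combination")
  bad <- !x %in% ok
  if (any(bad)) {
    ctr_stop("vocabulary", "validation",
             "unknown treatment arm token(s): %s (expected %s)",
             paste(unique(x[bad]), collapse = ", "), paste(ok, collapse = "/"))
  }
  x
}

BUNDLED_COHORTS <- "charite2012"
BUNDLED_CONTINGENCIES <- c("kern1990_total", "kern1990_ovarian",
                           "kern1990_single_agent", "kern1990_combination",
                           "charite2012_total", "charite2012_single_agent",
                           "charite2012_combination")

#' List bundled datasets
#'
#' @return Named list with the bundled cohort names and contingency names
#'   accepted by [load_cohort()] and [load_contingency()]. The
#'   `charite2012_*` contingencies are derived on the fly by tabulating the
#'   bundled cohort; the `kern1990_*` tables are the historical counts from
#'   the 1990 extreme-drug-resistance study, stored as printed.
#' @export
bundled_datasets <- function() {
  list(cohorts = BUNDLED_COHORTS, contingencies = BUNDLED_CONTINGENCIES)
}

validate_cohort <- function(cohort, source = "cohort") {
  required <- c("patient_id", "arm", "drug_a", "class_a", "drug_b", "class_b",
                "avastin", "response")
  missing <- setdiff(required, names(cohort))
  if (length(missing)) {
    ctr_stop("parse", "validation", "%s lacks column(s): %s", source,
             paste(missing, collapse = ", "))
  }
  if (nrow(cohort) == 0L) {
    ctr_stop("parse", "validation", "%s has no rows", source)
  }
  if (anyDuplicated(cohort$patient_id)) {
    ctr_stop("consistency", "validation", "%s has duplicated patient_id",
             source)
  }
  cohort$arm <- normalise_arm(cohort$arm)
  cohort$drug_a <- normalise_drug(cohort$drug_a)
  cohort$drug_b <- normalise_drug(cohort$drug_b)
  cohort$class_a <- as_resistance_class(cohort$class_a)
  cohort$class_b <- as_resistance_class(cohort$class_b)
  cohort$response <- normalise_response(cohort$response)
  av <- tolower(trimws(as.character(cohort$avastin)))
  av_map <- c("yes" = TRUE, "no" = FALSE, "true" = TRUE, "false" = FALSE)
  if (any(!av %in% names(av_map))) {
    ctr_stop("vocabulary", "validation",
             "avastin column must be yes/no (row(s): %s)",
             paste(which(!av %in% names(av_map)), collapse = ", "))
  }
  cohort$avastin <- unname(av_map[av])

  single <- cohort$arm != "combination"
  bad_single <- single & (!is.na(cohort$drug_b) | !is.na(cohort$class_b))
  if (any(bad_single)) {
    ctr_stop("consistency", "validation",
             "single-agent row(s) carry a second drug: %s",
             paste(which(bad_single), collapse = ", "))
  }
  bad_combo <- !single & (is.na(cohort$drug_b) | is.na(cohort$class_b))
  if (any(bad_combo)) {
    ctr_stop("consistency", "validation",
             "combination row(s) lack a second classified drug: %s",
             paste(which(bad_combo), collapse = ", "))
  }
  bad_first <- is.na(cohort$drug_a) | is.na(cohort$class_a)
  if (any(bad_first)) {
    ctr_stop("consistency", "validation",
             "row(s) lack the first tested drug or its class: %s",
             paste(which(bad_first), collapse = ", "))
  }
  wrong_av <- (cohort$arm == "mono_plus_avastin") != cohort$avastin
  if (any(wrong_av)) {
    ctr_stop("consistency", "validation",
             "avastin flag inconsistent with arm (row(s): %s)",
             paste(which(wrong_av), collapse = ", "))
  }
  if ("score" %in% names(cohort)) {
    cohort$score <- suppressWarnings(as.integer(cohort$score))
  }
  cohort
}

#' Load a patient cohort
#'
#' Either the bundled 52-patient ovarian-cancer cohort (`"charite2012"`:
#' 16 monotherapy, 3 monotherapy-plus-bevacizumab and 33 two-drug
#' combination patients, each with per-drug resistance classes and the
#' clinical response label) or a CSV file with header
#' `patient_id,arm,drug_a,class_a,drug_b,class_b,avastin,response`.
#' An optional trailing `score` column (the recorded combination score) is
#' preserved when present. Responder means clinical complete or partial
#' response; non-responder means stable or progressive disease — the label
#' is an input, never computed.
#'
#' @param source Bundled cohort name or path to a cohort CSV.
#' @return Validated cohort data frame (classes as ordered factors,
#'   `avastin` logical).
#' @examples
#' cohort <- load_cohort("charite2012")
#' table(cohort$arm)
#' @export
load_cohort <- function(source = "charite2012") {
  if (source %in% BUNDLED_COHORTS) {
    path <- system.file("extdata", paste0(source, "_cohort.csv"),
                        package = "ctrtest", mustWork = TRUE)
  } else {
    path <- source
    if (!file.exists(path)) {
      ctr_stop("parse", "validation",
               "'%s' is neither a bundled cohort (%s) nor an existing file",
               source, paste(BUNDLED_COHORTS, collapse = ", "))
    }
  }
  cohort <- tryCatch(read.csv(path, stringsAsFactors = FALSE,
                              na.strings = c("NA", "")),
                     error = function(e) {
                       ctr_stop("parse", "validation",
                                "cannot parse cohort file %s: %s", path,
                                conditionMessage(e))
                     })
  validate_cohort(cohort, source = path)
}

#' Write a cohort CSV
#'
#' @param cohort Cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  out$avastin <- ifelse(cohort$avastin, "yes", "no")
  for (col in c("class_a", "class_b")) out[[col]] <- as.character(out[[col]])
  write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Load an ordinal contingency table
#'
#' Accepts a bundled name (see [bundled_datasets()]) or a CSV path with
#' header `label,class,responders,n`. The bundled `kern1990_*` tables are
#' the historical 1990 counts (450 mixed-tumor samples and subsets); the
#' `charite2012_*` names tabulate the bundled cohort on the fly.
#'
#' @param source Bundled contingency name or CSV path.
#' @param label When reading a file holding several labelled tables, which
#'   label to extract (unneeded when the file holds exactly one).
#' @return An [ordinal_contingency()].
#' @examples
#' load_contingency("kern1990_total")
#' @export
load_contingency <- function(source, label = NULL) {
  if (source %in% BUNDLED_CONTINGENCIES) {
    if (startsWith(source, "charite2012")) {
      arm <- sub("^charite2012_?", "", source)
      if (arm == "total") arm <- "all"
      return(tabulate_cohort(load_cohort("charite2012"), arm = arm,
                             label = source))
    }
    path <- system.file("extdata", "kern1990_contingencies.csv",
                        package = "ctrtest", mustWork = TRUE)
    label <- source
  } else {
    path <- source
    if (!file.exists(path)) {
      ctr_stop("parse", "validation",
               "'%s' is neither a bundled contingency (%s) nor an existing file",
               source, paste(BUNDLED_CONTINGENCIES, collapse = ", "))
    }
  }
  raw <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("label", "class", "responders", "n")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    ctr_stop("parse", "validation",
             "contingency file lacks column(s): %s",
             paste(missing, collapse = ", "))
  }
  if (!is.null(label)) {
    raw <- raw[raw$label == label, , drop = FALSE]
    if (nrow(raw) == 0L) {
      ctr_stop("parse", "validation", "no rows with label '%s' in %s",
               label, path)
    }
  } else if (length(unique(raw$label)) > 1L) {
    ctr_stop("parse", "validation",
             "%s holds several tables (%s); pass `label`", path,
             paste(unique(raw$label), collapse = ", "))
  }
  ordinal_contingency(raw$responders, raw$n, classes = raw$class,
                      label = unique(raw$label))
}

#' Write a contingency CSV
#'
#' @param tab An [ordinal_contingency()].
#' @param path Output path.
#' @param label Label written to the `label` column; defaults to the table's
#'   own label.
#' @return `path`, invisibly.
#' @export
write_contingency <- function(tab, path, label = NULL) {
  tab <- as_ordinal_contingency(tab)
  if (is.null(label)) label <- attr(tab, "label")
  if (is.null(label)) label <- "contingency"
  out <- data.frame(label = label, class = as.character(tab$class),
                    responders = tab$responders, n = tab$n,
                    stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
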