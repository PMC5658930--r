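# Additive 0-4 scoring of two-drug combinations.

# score -> combined class: 0 = ER, 1-2 = MR, 3-4 = SR
combined_class_from_score <- function(score) {
  score <- as.integer(score)
  if (any(!is.na(score) & (score < 0L | score > 4L))) {
    ctr_stop("contract", "validation", "combination score must be in 0..4")
  }
  factor(c("ER", "MR", "MR", "SR", "SR")[score + 1L],
         levels = resistance_levels(), ordered = TRUE)
}

#' Score a two-drug combination
#'
#' Each single-drug class carries a score (ER = 0, MR = 1, SR = 2); the
#' combination score is the sum of the two single scores, giving 0–4, and is
#' mapped back to a combination-level class: scores 3–4 are SR, 1–2 are MR,
#' 0 is ER. The operation is symmetric in the two drugs.
#'
#' @param class_a,class_b Single-drug resistance classes (anything accepted
#'   by [as_resistance_class()]); recycled to a common length.
#' @return Data frame with columns `class_a`, `class_b`, `score` (integer
#'   0–4) and `combined_class` (ordered factor).
#' @examples
#' score_combination("SR", "ER")   # score 2, combined class MR
#' score_combination("SR", "SR")   # score 4, combined class SR
#' @export
score_combination <- function(class_a, class_b) {
  a <- as_resistance_class(class_a)
  b <- as_resistance_class(class_b)
  r <- recycle_args(a, b)
  a <- r[[1]]; b <- r[[2]]
  if (anyNA(a) || anyNA(b)) {
    ctr_stop("contract", "validation",
             "both single-drug classes are required for combination scoring")
  }
  score <- class_score(a) + class_score(b)
  data.frame(class_a = a, class_b = b, score = score,
             combined_class = combined_class_from_score(score))
}

#' Overall resistance class of each patient record
#'
#' Dispatch over treatment arms: monotherapy (with or without bevacizumab)
#' takes the single tested drug's class unchanged; two-drug combinations take
#' the combination class from [score_combination()]. Bevacizumab (Avastin) is
#' carried as metadata only and is never a scored drug.
#'
#' @param cohort Cohort data frame in the layout of [load_cohort()]:
#'   columns `drug_a`, `class_a` and (empty for single-agent rows) `drug_b`,
#'   `class_b`.
#' @return Ordered resistance-class factor, one element per row.
#' @examples
#' cohort <- load_cohort("charite2012")
#' table(overall_class(cohort), cohort$arm)
#' @export
overall_class <- function(cohort) {
  for (col in c("drug_a", "class_a")) {
    if (!col %in% names(cohort)) {
      ctr_stop("parse", "validation", "cohort lacks column '%s'", col)
    }
  }
  drug_b <- if ("drug_b" %in% names(cohort)) as.character(cohort$drug_b) else
    rep(NA_character_, nrow(cohort))
  class_b <- if ("class_b" %in% names(cohort)) cohort$class_b else
    rep(NA_character_, nrow(cohort))

  scored_av <- (!is.na(cohort$drug_a) & cohort$drug_a == "Avastin") |
    (!is.na(drug_b) & drug_b == "Avastin")
  if (any(scored_av)) {
    ctr_stop("contract", "validation",
             "Avastin is metadata, never a scored drug (row(s): %s)",
             paste(which(scored_av), collapse = ", "))
  }

  single <- is.na(drug_b) | drug_b == ""
  class_a <- as_resistance_class(cohort$class_a)
  no_drug <- (is.na(cohort$drug_a) | cohort$drug_a == "") | is.na(class_a)
  if (any(no_drug)) {
    ctr_stop("unsupported_regimen", "validation",
             "row(s) without a tested, classified drug: %s",
             paste(which(no_drug), collapse = ", "))
  }

  out <- class_a
  if (any(!single)) {
    out[!single] <- score_combination(class_a[!single],
                                      class_b[!single])$combined_class
  }
  out
}
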