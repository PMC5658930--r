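# PCI computation and population-relative resistance classification.

#' Percent cell growth inhibition from scintillation counts
#'
#' A well's counts per minute (cpm) are proportional to tritiated-thymidine
#' incorporation, i.e. to the DNA synthesis of surviving tumor cells. Two
#' controls anchor the scale: a lethal drug dose (positive control, maximal
#' kill) and no drug (negative control, unimpeded growth). Under the default
#' `"inhibition"` convention
#'
#' \deqn{PCI = \frac{cpm_{neg} - cpm_{treated}}{cpm_{neg} - cpm_{pos}}}
#'
#' so a fully effective drug (treated well equals the lethal control) gives
#' PCI = 1 and an ineffective drug gives PCI = 0. The `"printed"` convention
#' is the complementary surviving fraction
#' `(cpm_treated - cpm_pos) / (cpm_neg - cpm_pos)`; the two satisfy
#' `pci_printed = 1 - pci_inhibition`. Only the inhibition convention makes
#' high PCI mean "sensitive", which is what the SR/MR/ER classification
#' assumes, so it is the default.
#'
#' Values slightly outside \[0, 1\] can arise from counting noise (a treated
#' well colder than the lethal control, or hotter than the no-drug control);
#' they are retained, not clipped, and flagged with a warning.
#'
#' @param cpm_treated Non-negative counts per minute of the drug-treated
#'   well(s).
#' @param cpm_pos Non-negative cpm of the lethal-dose positive control.
#' @param cpm_neg Non-negative cpm of the no-drug negative control; must
#'   exceed `cpm_pos`, otherwise the assay is invalid.
#' @param convention `"inhibition"` (default) or `"printed"`; see Details.
#' @param sample_id Optional identifiers used in error/warning messages.
#' @param warn_out_of_range Warn when PCI falls outside \[0, 1\]?
#' @return Numeric vector of PCI values.
#' @examples
#' compute_pci(600, cpm_pos = 100, cpm_neg = 1100)   # 0.5
#' compute_pci(100, cpm_pos = 100, cpm_neg = 1100)   # 1: full kill
#' @export
compute_pci <- function(cpm_treated, cpm_pos, cpm_neg,
                        convention = c("inhibition", "printed"),
                        sample_id = NULL, warn_out_of_range = TRUE) {
  convention <- match.arg(convention)
  a <- recycle_args(as.numeric(cpm_treated), as.numeric(cpm_pos),
                    as.numeric(cpm_neg))
  cpm_treated <- a[[1]]; cpm_pos <- a[[2]]; cpm_neg <- a[[3]]
  ids <- if (is.null(sample_id)) as.character(seq_along(cpm_treated)) else
    rep_len(as.character(sample_id), length(cpm_treated))

  bad <- !is.finite(cpm_treated) | !is.finite(cpm_pos) | !is.finite(cpm_neg) |
    cpm_treated < 0 | cpm_pos < 0 | cpm_neg < 0
  if (any(bad)) {
    ctr_stop("invalid_assay", "validation",
             "cpm values must be finite and non-negative (sample(s): %s)",
             paste(unique(ids[bad]), collapse = ", "))
  }
  degen <- cpm_neg <= cpm_pos
  if (any(degen)) {
    ctr_stop("invalid_assay", "validation",
             paste0("degenerate controls: negative control must exceed the ",
                    "lethal-dose positive control (sample(s): %s)"),
             paste(unique(ids[degen]), collapse = ", "))
  }

  surviving <- (cpm_treated - cpm_pos) / (cpm_neg - cpm_pos)
  pci <- if (convention == "inhibition") 1 - surviving else surviving
  out <- pci < 0 | pci > 1
  if (warn_out_of_range && any(out)) {
    ctr_warn("pci_range",
             "%d PCI value(s) outside [0, 1] retained (sample(s): %s)",
             sum(out), paste(unique(ids[out]), collapse = ", "))
  }
  pci
}

# Validate an assay data.frame (one row per well or averaged measurement).
validate_assay <- function(assay) {
  required <- c("sample_id", "drug", "cpm_treated", "cpm_pos", "cpm_neg")
  missing <- setdiff(required, names(assay))
  if (length(missing)) {
    ctr_stop("parse", "validation",
             "assay table lacks column(s): %s", paste(missing, collapse = ", "))
  }
  if (nrow(assay) == 0L) {
    ctr_stop("parse", "validation", "assay table is empty")
  }
  assay
}

#' Read an assay CSV
#'
#' Expects header `sample_id,drug,cpm_treated,cpm_pos,cpm_neg`, one row per
#' well or per averaged measurement, UTF-8, dot decimal separator.
#'
#' @param path Path to a CSV file.
#' @return Validated data frame with normalised drug names.
#' @export
read_assay <- function(path) {
  if (!file.exists(path)) {
    ctr_stop("parse", "validation", "assay file not found: %s", path)
  }
  assay <- read.csv(path, stringsAsFactors = FALSE)
  assay <- validate_assay(assay)
  assay$drug <- normalise_drug(assay$drug)
  assay
}

#' PCI table from raw assay measurements
#'
#' Replicate wells for the same sample and drug are averaged on the cpm scale
#' (treated and both controls) before the PCI is computed, the simplest
#' faithful reduction of multi-well protocols.
#'
#' @param assay Data frame with columns `sample_id`, `drug`, `cpm_treated`,
#'   `cpm_pos`, `cpm_neg`.
#' @inheritParams compute_pci
#' @return Data frame with columns `sample_id`, `drug`, `pci`.
#' @examples
#' assay <- data.frame(sample_id = "s1", drug = "Carboplatin",
#'                     cpm_treated = c(580, 620), cpm_pos = 100,
#'                     cpm_neg = 1100)
#' assay_pci(assay)  # one averaged row, pci 0.5
#' @export
assay_pci <- function(assay, convention = c("inhibition", "printed"),
                      warn_out_of_range = TRUE) {
  convention <- match.arg(convention)
  assay <- validate_assay(assay)
  assay$drug <- normalise_drug(assay$drug)
  agg <- aggregate(assay[c("cpm_treated", "cpm_pos", "cpm_neg")],
                   by = list(sample_id = as.character(assay$sample_id),
                             drug = as.character(assay$drug)),
                   FUN = mean)
  agg <- agg[order(agg$sample_id, agg$drug), , drop = FALSE]
  pci <- compute_pci(agg$cpm_treated, agg$cpm_pos, agg$cpm_neg,
                     convention = convention, sample_id = agg$sample_id,
                     warn_out_of_range = warn_out_of_range)
  out <- data.frame(sample_id = agg$sample_id, drug = agg$drug, pci = pci,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Build a per-drug reference panel
#'
#' The class boundaries for a drug are defined by the mean and standard
#' deviation of PCI values over a reference collection of tumor samples
#' treated with that drug. The standard deviation uses the n−1 (sample)
#' denominator.
#'
#' @param pci Numeric PCI values from at least two reference samples.
#' @param drug Drug name the values belong to.
#' @return One-row data frame `drug`, `mean_pci`, `sd_pci`, `n_samples`.
#' @examples
#' build_reference_panel(c(0.2, 0.4, 0.6, 0.8), "Carboplatin")
#' @export
build_reference_panel <- function(pci, drug) {
  pci <- as.numeric(pci)
  if (anyNA(pci) || any(!is.finite(pci))) {
    ctr_stop("contract", "validation", "reference PCI values must be finite")
  }
  if (length(pci) < 2L) {
    ctr_stop("insufficient_reference", "validation",
             "reference panel for %s needs at least 2 PCI values, got %d",
             drug, length(pci))
  }
  s <- sd(pci)
  if (s <= 0) {
    ctr_stop("degenerate_panel", "degenerate",
             "reference panel for %s has zero PCI variance", drug)
  }
  data.frame(drug = as.character(drug), mean_pci = mean(pci), sd_pci = s,
             n_samples = length(pci), stringsAsFactors = FALSE)
}

#' Build reference panels for every drug in a PCI table
#'
#' @param pci_tbl Data frame with columns `drug` and `pci` (e.g. from
#'   [assay_pci()]).
#' @return Data frame with one row per drug: `drug`, `mean_pci`, `sd_pci`,
#'   `n_samples`.
#' @export
build_reference_panels <- function(pci_tbl) {
  if (!all(c("drug", "pci") %in% names(pci_tbl))) {
    ctr_stop("parse", "validation", "need columns 'drug' and 'pci'")
  }
  parts <- lapply(split(pci_tbl$pci, pci_tbl$drug),
                  function(v) v)
  out <- do.call(rbind, Map(build_reference_panel, parts, names(parts)))
  rownames(out) <- NULL
  out[order(out$drug), , drop = FALSE]
}

#' Classify PCI values against a reference panel
#'
#' Relative to the reference mean m and standard deviation s for the drug:
#' slight resistance (SR) for `pci >= m`, extreme resistance (ER) for
#' `pci < m - s`, medium resistance (MR) in between. The boundary value
#' `pci == m - s` is MR by default (`er_boundary = "exclusive"`); setting
#' `er_boundary = "inclusive"` moves exactly that boundary case into ER.
#'
#' @param pci Numeric PCI values.
#' @param mean_pci,sd_pci Reference-population mean and standard deviation
#'   (sd must be positive).
#' @param er_boundary `"exclusive"` (default; ER is `pci < m - s`) or
#'   `"inclusive"` (ER is `pci <= m - s`).
#' @return Ordered resistance-class factor (`ER < MR < SR`).
#' @examples
#' classify_pci(c(0.75, 0.40, 0.25, 0.30), mean_pci = 0.5, sd_pci = 0.2)
#' @export
classify_pci <- function(pci, mean_pci, sd_pci,
                         er_boundary = c("exclusive", "inclusive")) {
  er_boundary <- match.arg(er_boundary)
  a <- recycle_args(as.numeric(pci), as.numeric(mean_pci), as.numeric(sd_pci))
  pci <- a[[1]]; m <- a[[2]]; s <- a[[3]]
  if (any(!is.finite(pci)) || any(!is.finite(m)) || any(!is.finite(s))) {
    ctr_stop("contract", "validation", "pci, mean and sd must be finite")
  }
  if (any(s <= 0)) {
    ctr_stop("degenerate_panel", "degenerate",
             "reference sd must be positive for classification")
  }
  lower <- m - s
  er <- if (er_boundary == "exclusive") pci < lower else pci <= lower
  cls <- ifelse(pci >= m, "SR", ifelse(er, "ER", "MR"))
  as_resistance_class(cls)
}

#' Classify a PCI table against a panel table
#'
#' Joins PCI values to reference panels by drug and applies [classify_pci()].
#' A drug without a panel is a vocabulary error — classification is only
#' defined relative to a reference population for that drug.
#'
#' @param pci_tbl Data frame with columns `sample_id`, `drug`, `pci`.
#' @param panels Data frame with columns `drug`, `mean_pci`, `sd_pci`
#'   (e.g. from [build_reference_panels()] or [read_reference_panel()]).
#' @inheritParams classify_pci
#' @return `pci_tbl` with an added ordered-factor column `class`.
#' @export
classify_assay <- function(pci_tbl, panels,
                           er_boundary = c("exclusive", "inclusive")) {
  er_boundary <- match.arg(er_boundary)
  if (!all(c("drug", "pci") %in% names(pci_tbl))) {
    ctr_stop("parse", "validation", "need columns 'drug' and 'pci'")
  }
  if (!all(c("drug", "mean_pci", "sd_pci") %in% names(panels))) {
    ctr_stop("parse", "validation",
             "panels need columns 'drug', 'mean_pci', 'sd_pci'")
  }
  idx <- match(pci_tbl$drug, panels$drug)
  if (anyNA(idx)) {
    ctr_stop("vocabulary", "validation",
             "no reference panel for drug(s): %s",
             paste(unique(pci_tbl$drug[is.na(idx)]), collapse = ", "))
  }
  pci_tbl$class <- classify_pci(pci_tbl$pci, panels$mean_pci[idx],
                                panels$sd_pci[idx], er_boundary = er_boundary)
  pci_tbl
}

#' Read / write a reference panel CSV
#'
#' Panel files have header `drug,mean_pci,sd_pci,n_samples`.
#'
#' @param path Path to a CSV file.
#' @return `read_reference_panel()` returns the validated panel data frame;
#'   `write_reference_panel()` returns `path` invisibly.
#' @export
read_reference_panel <- function(path) {
  if (!file.exists(path)) {
    ctr_stop("parse", "validation", "panel file not found: %s", path)
  }
  p <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("drug", "mean_pci", "sd_pci", "n_samples")
  missing <- setdiff(required, names(p))
  if (length(missing)) {
    ctr_stop("parse", "validation",
             "panel file lacks column(s): %s", paste(missing, collapse = ", "))
  }
  if (any(!is.finite(p$sd_pci)) || any(p$sd_pci <= 0)) {
    ctr_stop("degenerate_panel", "degenerate",
             "panel sd_pci must be positive")
  }
  p$drug <- normalise_drug(p$drug)
  p
}

#' @rdname read_reference_panel
#' @param panels Panel data frame to write.
#' @export
write_reference_panel <- function(panels, path) {
  write.csv(panels, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
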