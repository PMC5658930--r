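# Agreement between predicted resistance class and clinical response:
# per-class exact binomial intervals, ordinal ROC/AUC, DeLong variance.

#' Ordinal contingency table of responders per class
#'
#' The evaluation substrate: for each (ordered) predictor class, the number
#' of responders and the total number of patients. Classes from the
#' resistance vocabulary are ordered ER < MR < SR automatically; any other
#' class labels (e.g. combination scores 0–4) are ordered by `class_levels`,
#' worst prognosis first.
#'
#' @param responders Integer responder counts per class.
#' @param n Integer total patients per class (`n >= responders`).
#' @param classes Class labels, one per count.
#' @param class_levels Optional explicit level order (increasing, i.e. most
#'   resistant first). Defaults to `ER < MR < SR` for resistance labels and
#'   `sort(unique(classes))` otherwise.
#' @param label Optional dataset name, carried into reports.
#' @return Data frame of class `ordinal_contingency` with columns `class`
#'   (ordered factor), `responders`, `n`.
#' @examples
#' ordinal_contingency(responders = c(18, 7, 0), n = c(19, 11, 3),
#'                     classes = c("SR", "MR", "ER"), label = "combination")
#' @export
ordinal_contingency <- function(responders, n, classes = c("SR", "MR", "ER"),
                                class_levels = NULL, label = NULL) {
  responders <- as.integer(responders)
  n <- as.integer(n)
  classes <- as.character(classes)
  if (length(responders) != length(n) || length(n) != length(classes)) {
    ctr_stop("contract", "validation",
             "responders, n and classes must have equal length")
  }
  if (anyNA(responders) || anyNA(n) || any(responders < 0L)) {
    ctr_stop("consistency", "validation", "counts must be non-negative integers")
  }
  if (any(responders > n)) {
    ctr_stop("consistency", "validation",
             "responders cannot exceed n (class %s)",
             paste(classes[responders > n], collapse = ", "))
  }
  if (anyDuplicated(classes)) {
    ctr_stop("consistency", "validation", "duplicated class labels")
  }
  if (sum(n) == 0L) {
    ctr_stop("empty_cohort", "validation", "contingency has no patients")
  }
  if (is.null(class_levels)) {
    class_levels <- if (all(classes %in% resistance_levels()))
      resistance_levels() else sort(unique(classes))
  }
  if (!all(classes %in% class_levels)) {
    ctr_stop("vocabulary", "validation", "class labels outside class_levels")
  }
  out <- data.frame(class = factor(classes, levels = class_levels,
                                   ordered = TRUE),
                    responders = responders, n = n)
  attr(out, "label") <- label
  class(out) <- c("ordinal_contingency", "data.frame")
  out
}

as_ordinal_contingency <- function(tab) {
  if (inherits(tab, "ordinal_contingency")) return(tab)
  if (!is.data.frame(tab) ||
      !all(c("class", "responders", "n") %in% names(tab))) {
    ctr_stop("contract", "validation",
             "expected an ordinal_contingency or a data frame with columns class, responders, n")
  }
  ordinal_contingency(tab$responders, tab$n, as.character(tab$class),
                      label = attr(tab, "label"))
}

#' Tabulate a cohort into an ordinal contingency
#'
#' Derives each patient's overall class (see [overall_class()]) and counts
#' responders and totals per class. The `single_agent` filter pools the
#' monotherapy and monotherapy-plus-bevacizumab arms, mirroring how the two
#' small single-agent groups are combined before comparison with the
#' combination-therapy group.
#'
#' @param cohort Cohort data frame as returned by [load_cohort()].
#' @param arm `"all"`, `"single_agent"` (mono plus mono_plus_avastin) or
#'   `"combination"`.
#' @param label Optional dataset name; defaults to the arm filter.
#' @return An [ordinal_contingency()] with one row per class SR, MR, ER.
#' @examples
#' tabulate_cohort(load_cohort("charite2012"), arm = "combination")
#' @export
tabulate_cohort <- function(cohort, arm = c("all", "single_agent",
                                            "combination"),
                            label = NULL) {
  arm <- match.arg(arm)
  keep <- switch(arm,
                 all = rep(TRUE, nrow(cohort)),
                 single_agent = cohort$arm %in%
                   c("mono", "mono_plus_avastin"),
                 combination = cohort$arm == "combination")
  sub <- cohort[keep, , drop = FALSE]
  if (nrow(sub) == 0L) {
    ctr_stop("empty_cohort", "validation",
             "no patients left after arm filter '%s'", arm)
  }
  cls <- overall_class(sub)
  resp <- normalise_response(sub$response) == "responder"
  lev <- c("SR", "MR", "ER")  # Table-style display order, best class first
  responders <- vapply(lev, function(l) sum(resp & cls == l), 1L)
  totals <- vapply(lev, function(l) sum(cls == l), 1L)
  ordinal_contingency(responders, totals, classes = lev,
                      label = if (is.null(label)) arm else label)
}

#' Contingency over combination scores 0–4
#'
#' Five-level variant of [tabulate_cohort()] for the combination arm, using
#' the raw additive score as the ordinal predictor instead of the collapsed
#' three classes.
#'
#' @inheritParams tabulate_cohort
#' @return An [ordinal_contingency()] with classes `"0"`–`"4"`.
#' @export
tabulate_scores <- function(cohort, label = "combination scores") {
  sub <- cohort[cohort$arm == "combination", , drop = FALSE]
  if (nrow(sub) == 0L) {
    ctr_stop("empty_cohort", "validation", "no combination-arm patients")
  }
  sc <- score_combination(sub$class_a, sub$class_b)$score
  resp <- normalise_response(sub$response) == "responder"
  lev <- as.character(4:0)
  responders <- vapply(lev, function(l) sum(resp & sc == as.integer(l)), 1L)
  totals <- vapply(lev, function(l) sum(sc == as.integer(l)), 1L)
  ordinal_contingency(responders, totals, classes = lev,
                      class_levels = as.character(0:4), label = label)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' The exact interval from beta-distribution quantiles: with `x` successes
#' out of `n`, the lower bound is the `alpha/2` quantile of
#' `Beta(x, n - x + 1)` (0 when `x = 0`) and the upper bound the
#' `1 - alpha/2` quantile of `Beta(x + 1, n - x)` (1 when `x = n`). These
#' intervals are conservative: empirical coverage is at least the nominal
#' level.
#'
#' @param x Number of successes (responders), `0 <= x <= n`.
#' @param n Number of trials (patients in the class), `n >= 1`.
#' @param level Confidence level, default 0.95.
#' @return Data frame with columns `x`, `n`, `point`, `lower`, `upper`,
#'   `level`, `method`.
#' @examples
#' clopper_pearson(22, 28)   # point 0.786, CI (0.590, 0.917)
#' clopper_pearson(0, 7)     # one-sided: (0, 0.410)
#' @export
clopper_pearson <- function(x, n, level = 0.95) {
  a <- recycle_args(as.integer(x), as.integer(n))
  x <- a[[1]]; n <- a[[2]]
  if (any(n < 1L)) {
    ctr_stop("undefined_proportion", "degenerate",
             "proportion undefined for n = 0")
  }
  if (any(x < 0L) || any(x > n)) {
    ctr_stop("consistency", "validation", "need 0 <= x <= n")
  }
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    ctr_stop("config", "validation", "level must be in (0, 1)")
  }
  alpha <- 1 - level
  lower <- ifelse(x == 0L, 0, qbeta(alpha / 2, x, n - x + 1))
  upper <- ifelse(x == n, 1, qbeta(1 - alpha / 2, x + 1, n - x))
  data.frame(x = x, n = n, point = x / n, lower = lower, upper = upper,
             level = level, method = "clopper-pearson",
             stringsAsFactors = FALSE)
}

#' Round a proportion to whole percent, half away from zero
#'
#' Table-style reporting rounds 0.5 up (so 64.5% prints as 65), unlike R's
#' banker's rounding. A tiny epsilon guards against binary representation of
#' exact halves.
#'
#' @param p Proportions in \[0, 1\].
#' @return Integer percents.
#' @export
percent_round <- function(p) {
  as.integer(floor(100 * p + 0.5 + 1e-9))
}

# counts ordered worst class -> best class
auc_counts <- function(tab) {
  tab <- as_ordinal_contingency(tab)
  ord <- order(tab$class)
  pos <- tab$responders[ord]
  neg <- tab$n[ord] - tab$responders[ord]
  list(pos = pos, neg = neg, np = sum(pos), nn = sum(neg))
}

#' Ties-corrected ordinal AUC from a contingency table
#'
#' The probability that a randomly chosen responder has a higher (more
#' drug-sensitive) class than a randomly chosen non-responder, with half
#' credit for ties — the ties-corrected Mann-Whitney statistic computed
#' exactly from the class counts:
#' \deqn{AUC = \frac{\#\{resp > non\} + 0.5\,\#\{resp = non\}}{n_{pos}\,n_{neg}}}
#'
#' @param tab An [ordinal_contingency()].
#' @return The AUC as a single number in \[0, 1\].
#' @examples
#' tab <- ordinal_contingency(c(18, 7, 0), c(19, 11, 3), c("SR", "MR", "ER"))
#' ordinal_auc(tab)   # 0.85
#' @export
ordinal_auc <- function(tab) {
  cc <- auc_counts(tab)
  if (cc$np == 0L || cc$nn == 0L) {
    ctr_stop("degenerate_roc", "degenerate",
             "AUC needs at least one responder and one non-responder")
  }
  k <- length(cc$pos)
  neg_below <- c(0, cumsum(cc$neg))[seq_len(k)]
  concordant <- sum(cc$pos * neg_below)
  ties <- sum(cc$pos * cc$neg)
  (concordant + 0.5 * ties) / (cc$np * cc$nn)
}

#' DeLong variance and confidence interval for the ordinal AUC
#'
#' Nonparametric AUC variance from per-subject placement values. A
#' responder's placement is the fraction of non-responders in strictly worse
#' classes plus half the fraction tied; symmetrically for non-responders.
#' The variance is `var(V10)/n_pos + var(V01)/n_neg` with n−1 denominators,
#' and the CI is the normal approximation `auc ± z * se`, clipped to
#' \[0, 1\] (a clipped upper bound of exactly 1 is reported as 1).
#'
#' @inheritParams ordinal_auc
#' @param level Confidence level, default 0.95.
#' @return Object of class `ctr_auc`: a list with `auc`, `variance`,
#'   `ci_lower`, `ci_upper`, `level`, `n_pos`, `n_neg`, `roc_points`
#'   and `label`.
#' @examples
#' tab <- ordinal_contingency(c(18, 7, 0), c(19, 11, 3), c("SR", "MR", "ER"))
#' delong_ci(tab)   # AUC 0.85, 95% CI (0.6942, 1)
#' @export
delong_ci <- function(tab, level = 0.95) {
  tab <- as_ordinal_contingency(tab)
  cc <- auc_counts(tab)
  if (cc$np == 0L || cc$nn == 0L) {
    ctr_stop("degenerate_roc", "degenerate",
             "AUC needs at least one responder and one non-responder")
  }
  if (cc$np < 2L || cc$nn < 2L) {
    ctr_stop("variance_undefined", "degenerate",
             "DeLong variance needs at least 2 subjects per group")
  }
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    ctr_stop("config", "validation", "level must be in (0, 1)")
  }
  k <- length(cc$pos)
  neg_below <- c(0, cumsum(cc$neg))[seq_len(k)]
  pos_above <- rev(c(0, cumsum(rev(cc$pos))))[-1]
  # placement of a responder in class i among non-responders (higher = better)
  v10 <- (neg_below + 0.5 * cc$neg) / cc$nn
  # placement of a non-responder in class i among responders
  v01 <- (pos_above + 0.5 * cc$pos) / cc$np
  V10 <- rep(v10, cc$pos)
  V01 <- rep(v01, cc$neg)
  auc <- mean(V10)
  variance <- var(V10) / cc$np + var(V01) / cc$nn
  z <- qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(variance)
  structure(list(auc = auc, variance = variance,
                 ci_lower = max(0, auc - half),
                 ci_upper = min(1, auc + half),
                 level = level, n_pos = cc$np, n_neg = cc$nn,
                 roc_points = roc_points(tab),
                 label = attr(tab, "label")),
            class = "ctr_auc")
}

#' @export
print.ctr_auc <- function(x, digits = 4, ...) {
  lbl <- if (is.null(x$label)) "" else paste0(" (", x$label, ")")
  cat(sprintf("Ordinal ROC%s: AUC = %s, %g%% CI (DeLong) = %s-%s\n",
              lbl, format(round(x$auc, digits)), 100 * x$level,
              format(round(x$ci_lower, digits)),
              format(round(x$ci_upper, digits))))
  cat(sprintf("  responders = %d, non-responders = %d, variance = %s\n",
              x$n_pos, x$n_neg, format(signif(x$variance, digits))))
  invisible(x)
}

#' ROC points for an ordinal contingency
#'
#' Sweeps the classification threshold from the strictest (call everything
#' non-responder) to the loosest, yielding one point per class plus the
#' origin. The trapezoidal area over these points equals [ordinal_auc()]
#' exactly.
#'
#' @inheritParams ordinal_auc
#' @return Data frame with columns `fpr`, `tpr`, starting at (0, 0) and
#'   ending at (1, 1), both coordinates non-decreasing.
#' @export
roc_points <- function(tab) {
  cc <- auc_counts(tab)
  if (cc$np == 0L || cc$nn == 0L) {
    ctr_stop("degenerate_roc", "degenerate",
             "ROC needs at least one responder and one non-responder")
  }
  # best class first
  pos <- rev(cc$pos); neg <- rev(cc$neg)
  data.frame(fpr = c(0, cumsum(neg) / cc$nn),
             tpr = c(0, cumsum(pos) / cc$np))
}

#' Plot a step ROC curve
#'
#' @param x A `ctr_auc` object from [delong_ci()].
#' @param ... Passed to [graphics::plot.default()].
#' @return `x`, invisibly.
#' @export
plot.ctr_auc <- function(x, ...) {
  p <- x$roc_points
  plot.default(p$fpr, p$tpr, type = "n", xlim = c(0, 1), ylim = c(0, 1),
               xlab = "False positive rate", ylab = "True positive rate",
               main = if (is.null(x$label)) "ROC" else x$label, ...)
  abline(0, 1, col = "grey70", lty = 2)
  lines(p$fpr, p$tpr, type = "b", pch = 16)
  legend("bottomright", bty = "n",
         legend = sprintf("AUC %.4f (%g%% CI %.4f-%.4f)", x$auc,
                          100 * x$level, x$ci_lower, x$ci_upper))
  invisible(x)
}

#' Per-class accuracy table with exact intervals
#'
#' One row per class (best class first): responder count, total, the
#' responder proportion with its Clopper-Pearson interval, and the same three
#' quantities as half-up rounded whole percents for table-style display.
#' Intervals are unadjusted for multiplicity.
#'
#' @inheritParams delong_ci
#' @return Data frame with columns `dataset`, `class`, `resp`, `n`,
#'   `proportion`, `lower`, `upper`, `percent`, `percent_low`,
#'   `percent_high`.
#' @examples
#' class_accuracy_table(tabulate_cohort(load_cohort("charite2012"), "all"))
#' @export
class_accuracy_table <- function(tab, level = 0.95) {
  tab <- as_ordinal_contingency(tab)
  ord <- order(tab$class, decreasing = TRUE)
  cls <- as.character(tab$class)[ord]
  x <- tab$responders[ord]
  n <- tab$n[ord]
  keep <- n > 0L
  ci <- clopper_pearson(x[keep], n[keep], level = level)
  out <- data.frame(
    dataset = if (is.null(attr(tab, "label"))) NA_character_ else
      attr(tab, "label"),
    class = cls[keep], resp = x[keep], n = n[keep],
    proportion = ci$point, lower = ci$lower, upper = ci$upper,
    percent = percent_round(ci$point),
    percent_low = percent_round(ci$lower),
    percent_high = percent_round(ci$upper),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Evaluate a contingency: accuracy table plus ROC/AUC
#'
#' @inheritParams delong_ci
#' @return List of class `ctr_evaluation` with elements `contingency`,
#'   `accuracy` (see [class_accuracy_table()]) and `auc` (see [delong_ci()]).
#' @export
evaluate_contingency <- function(tab, level = 0.95) {
  tab <- as_ordinal_contingency(tab)
  structure(list(contingency = tab,
                 accuracy = class_accuracy_table(tab, level = level),
                 auc = delong_ci(tab, level = level)),
            class = "ctr_evaluation")
}

#' Evaluate a cohort end to end
#'
#' Tabulates the cohort under the arm filter and runs
#' [evaluate_contingency()].
#'
#' @inheritParams tabulate_cohort
#' @inheritParams delong_ci
#' @examples
#' ev <- evaluate_cohort(load_cohort("charite2012"), arm = "combination")
#' ev$auc
#' @export
evaluate_cohort <- function(cohort, arm = c("all", "single_agent",
                                            "combination"),
                            level = 0.95, label = NULL) {
  tab <- tabulate_cohort(cohort, arm = arm, label = label)
  evaluate_contingency(tab, level = level)
}

#' @export
print.ctr_evaluation <- function(x, ...) {
  lbl <- attr(x$contingency, "label")
  if (!is.null(lbl)) cat("Dataset:", lbl, "\n")
  cat("Per-class responder proportions (exact CIs):\n")
  print(x$accuracy[, c("class", "resp", "n", "percent", "percent_low",
                       "percent_high")], row.names = FALSE)
  print(x$auc)
  invisible(x)
}
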