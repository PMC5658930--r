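# Resistance classes and structured error conditions shared across modules.

#' Resistance class levels, in increasing order of in vitro sensitivity
#'
#' The three-tier classification used throughout the package: extreme
#' resistance (ER), medium resistance (MR) and slight resistance (SR).
#' The order ER < MR < SR matters: a "higher" class means the tumor cells
#' were more inhibited in vitro, i.e. the drug is more promising.
#'
#' @return Character vector `c("ER", "MR", "SR")`.
#' @export
resistance_levels <- function() c("ER", "MR", "SR")

#' Coerce to an ordered resistance-class factor
#'
#' @param x Character, factor or resistance-class vector. Tokens are matched
#'   case-insensitively against `ER`, `MR`, `SR`; `NA` is passed through.
#' @return Ordered factor with levels `ER < MR < SR`.
#' @examples
#' as_resistance_class(c("sr", "ER", NA))
#' @export
as_resistance_class <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  x <- toupper(trimws(as.character(x)))
  x[!is.na(x) & x == ""] <- NA_character_
  bad <- !is.na(x) & !(x %in% resistance_levels())
  if (any(bad)) {
    ctr_stop("vocabulary", "validation",
             "unknown resistance class token(s): %s",
             paste(unique(x[bad]), collapse = ", "))
  }
  factor(x, levels = resistance_levels(), ordered = TRUE)
}

#' Integer score of a resistance class
#'
#' ER scores 0, MR scores 1, SR scores 2. This is the per-drug score summed
#' by [score_combination()].
#'
#' @param cls Anything accepted by [as_resistance_class()].
#' @return Integer vector in `{0, 1, 2}`.
#' @examples
#' class_score(c("ER", "MR", "SR"))
#' @export
class_score <- function(cls) {
  as.integer(as_resistance_class(cls)) - 1L
}

#' Resistance class for a single-drug score
#'
#' Inverse of [class_score()] for scores 0–2.
#'
#' @param score Integer vector in `{0, 1, 2}`.
#' @return Ordered resistance-class factor.
#' @export
score_to_class <- function(score) {
  score <- as.integer(score)
  if (any(!is.na(score) & (score < 0L | score > 2L))) {
    ctr_stop("contract", "validation", "single-drug score must be 0, 1 or 2")
  }
  factor(resistance_levels()[score + 1L],
         levels = resistance_levels(), ordered = TRUE)
}

# Structured conditions. `kind` names the specific failure, `group` is either
# "validation" (bad input / contract breach) or "degenerate" (statistics
# undefined on this input). The CLI maps the groups to exit codes 2 and 3.
ctr_stop <- function(kind, group, fmt, ...) {
  msg <- sprintf(fmt, ...)
  cond <- structure(
    class = c(paste0("ctr_", kind, "_error"),
              paste0("ctr_", group, "_error"),
              "ctr_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

ctr_warn <- function(kind, fmt, ...) {
  msg <- sprintf(fmt, ...)
  warning(structure(
    class = c(paste0("ctr_", kind, "_warning"), "ctr_warning",
              "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Shared recycling helper: recycle length-1 arguments to a common length.
recycle_args <- function(...) {
  args <- list(...)
  n <- max(vapply(args, length, 1L))
  bad <- vapply(args, function(a) !(length(a) %in% c(1L, n)), TRUE)
  if (any(bad)) {
    ctr_stop("contract", "validation",
             "arguments must have length 1 or %d", n)
  }
  lapply(args, rep_len, length.out = n)
}
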