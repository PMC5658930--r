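# Shared oracles and in-code fixtures.

# Table of per-class responder counts for the seven evaluation datasets,
# as published (best class SR first).
published_tables <- function() {
  list(
    charite_total        = list(r = c(22, 9, 0), n = c(28, 17, 7)),
    charite_single_agent = list(r = c(4, 2, 0),  n = c(9, 6, 4)),
    charite_combination  = list(r = c(18, 7, 0), n = c(19, 11, 3)),
    kern_total           = list(r = c(115, 16, 1), n = c(222, 101, 127)),
    kern_ovarian         = list(r = c(14, 0, 0),   n = c(24, 11, 11)),
    kern_single_agent    = list(r = c(72, 9, 1),   n = c(151, 79, 115)),
    kern_combination     = list(r = c(43, 7, 0),   n = c(71, 22, 12))
  )
}

make_tab <- function(key, label = key) {
  t <- published_tables()[[key]]
  ordinal_contingency(t$r, t$n, classes = c("SR", "MR", "ER"), label = label)
}

# Expand an ordinal contingency into per-patient scores (higher = more
# sensitive class) and binary response.
expand_contingency <- function(tab) {
  ord <- order(tab$class)
  score <- as.integer(tab$class[ord]) - 1L
  pos <- tab$responders[ord]
  neg <- tab$n[ord] - tab$responders[ord]
  data.frame(score = c(rep(score, pos), rep(score, neg)),
             response = c(rep(1L, sum(pos)), rep(0L, sum(neg))))
}

# Brute-force pairwise AUC: all responder x non-responder pairs, half
# credit for ties. Independent of the counts-based implementation.
brute_force_auc <- function(tab) {
  d <- expand_contingency(tab)
  sp <- d$score[d$response == 1L]
  sn <- d$score[d$response == 0L]
  cmp <- outer(sp, sn, ">") + 0.5 * outer(sp, sn, "==")
  mean(cmp)
}

# Trapezoidal area under a (fpr, tpr) polyline.
trapezoid_area <- function(points) {
  sum(diff(points$fpr) * (utils::head(points$tpr, -1) +
                            utils::tail(points$tpr, -1)) / 2)
}

# Random small 3-class contingency with at least one responder and one
# non-responder.
random_contingency <- function() {
  repeat {
    n <- sample(0:15, 3, replace = TRUE)
    if (sum(n) == 0) next
    r <- vapply(n, function(k) if (k == 0) 0L else sample(0:k, 1), 1L)
    if (sum(r) > 0 && sum(n - r) > 0) {
      return(ordinal_contingency(r, n, classes = c("SR", "MR", "ER")))
    }
  }
}
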