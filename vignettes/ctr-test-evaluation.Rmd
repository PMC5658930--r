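---
title: "Evaluating an in vitro chemoresistance test against clinical response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating an in vitro chemoresistance test against clinical response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctrtest)
```

## The measurement model

A chemoresistance assay exposes disaggregated tumor cells to one drug per
well in soft agar, then measures tritiated-thymidine incorporation of the
surviving cells by scintillation counting. Each measurement is a triple of
counts per minute: the treated well (`cpm_treated`), a lethal-dose positive
control (`cpm_pos`, maximal kill) and a no-drug negative control
(`cpm_neg`, unimpeded growth). The percent cell growth inhibition is

$$\mathrm{PCI} = \frac{cpm_{neg} - cpm_{treated}}{cpm_{neg} - cpm_{pos}},$$

a dimensionless fraction that is 1 when the drug is as effective as the
lethal dose and 0 when it does nothing. The assay is only valid when
`cpm_neg > cpm_pos`; `compute_pci()` refuses degenerate controls, naming
the offending samples.

Two conventions circulate for this quantity. The surviving-fraction form
`(cpm_treated − cpm_pos)/(cpm_neg − cpm_pos)` is the exact complement of
the inhibition form above (`pci_printed = 1 − pci_inhibition`). Only the
inhibition form makes "high PCI" mean "drug works", which is what the
class definitions below assume, so it is the package default;
`convention = "printed"` selects the complement for users whose upstream
records use it. Because the classification is population-relative and both
conventions are affine images of each other, either convention yields the
same classes when used consistently for samples and reference panels.

Counting noise can push PCI slightly outside $[0, 1]$ (a treated well
colder than the lethal control, or warmer than the no-drug control). Such
values are retained and flagged with a warning, never clipped: clipping
would silently move mass onto the class boundaries. Replicate wells for
the same sample and drug are averaged on the cpm scale before the ratio is
formed (`assay_pci()`), the simplest reduction that respects the count
scale.

## Population-relative resistance classes

For each drug, a reference collection of tumors defines a mean $m$ and
sample standard deviation $s$ (n−1 denominator; `build_reference_panel()`
requires at least two values and positive spread) of PCI. A new tumor's
PCI is then classified:

* **SR** (slight resistance), $\mathrm{PCI} \ge m$ — the tumor is at least
  as inhibited as the average reference tumor; the drug looks promising;
* **ER** (extreme resistance), $\mathrm{PCI} < m - s$ — the tumor sits in
  the resistant tail; the drug is predicted to fail;
* **MR** (medium resistance) in between.

The boundary value $\mathrm{PCI} = m - s$ is assigned to MR by default.
The source descriptions of the ER cut-off disagree between "≤" and "<";
this is a measure-zero choice for continuous data, but it is made explicit
and configurable (`er_boundary = "inclusive"` moves exactly the boundary
case into ER), and the unit tests pin the default and verify that flipping
the rule changes only that case.

The classes are ordered ER < MR < SR and carry integer scores 0, 1, 2.
For a two-drug combination the single scores are summed (0–4) and mapped
back: 3–4 → SR, 1–2 → MR, 0 → ER. The map is commutative and monotone in
each argument; `score_combination()` implements it and the test suite
enumerates all nine ordered pairs. Bevacizumab is carried as regimen
metadata only — it is not assayed, so it never contributes a score, and
three-drug regimens are rejected rather than extrapolated: the additive
score is defined for pairs.

## Evaluating agreement with clinical response

Each patient contributes an overall class (the single tested drug's class
for monotherapy with or without bevacizumab, the combination class
otherwise) and a binary response label recorded from the clinic:
responder = complete or partial response, non-responder = stable or
progressive disease. The label is an input, never computed.

`tabulate_cohort()` reduces a cohort to the 3×2 ordinal contingency of
responders per class. Two statistics summarise it:

**Per-class exact intervals.** The responder proportion of each class gets
a Clopper-Pearson interval from beta quantiles: lower bound
$B_{\alpha/2}(x,\, n-x+1)$ (0 when $x = 0$), upper bound
$B_{1-\alpha/2}(x+1,\, n-x)$ (1 when $x = n$). These intervals are
conservative by construction — empirical coverage is at least nominal,
which the test suite checks by simulation. Table-style reports round
proportions to whole percent, half away from zero (`percent_round()`);
raw fractions are kept alongside. No multiplicity adjustment is applied —
the intervals are descriptive and marked unadjusted.

**Ordinal ROC/AUC.** With the class order SR > MR > ER as predictor and
responder as the positive label,

$$\mathrm{AUC} = \frac{\#\{\text{resp} > \text{non}\} +
 \tfrac12\#\{\text{resp} = \text{non}\}}{n_{pos}\, n_{neg}},$$

computed exactly from the counts (ties get half credit, the Mann-Whitney
convention; no continuity correction). The variance is DeLong's: each
responder's placement among non-responders and vice versa, with n−1
variance denominators, combined as $v_{10}/n_{pos} + v_{01}/n_{neg}$; the
CI is the normal approximation clipped to $[0, 1]$, so a small, strongly
separated sample can report an upper bound of exactly 1.
`roc_points()` returns the threshold-sweep curve; its trapezoidal area
equals the counts-based AUC identically, which the suite asserts on random
tables. The implementation is cross-checked in two independent ways: a
brute-force loop over all responder × non-responder pairs, and `pROC`'s
DeLong machinery on the expanded per-patient data.

The default predictor has three levels. Collapsing combination scores
3–4/1–2/0 before the ROC is a real modelling choice: the five-level score
predictor (`tabulate_scores()`, `--roc-levels 5`) generally yields a
different AUC (0.87 versus 0.85 on the bundled combination arm) because it
breaks ties the three-level view keeps. The three-level predictor is the
default because the classification — not the raw score — is the test
result acted on clinically.

## Bundled data

`load_cohort("charite2012")` returns the 52-patient ovarian-cancer cohort
(2010–2011 accruals, evaluated 2012): 16 monotherapy, 3 monotherapy plus
bevacizumab and 33 carboplatin-based two-drug combination patients, each
with per-drug classes, the recorded combination score and the response
label. One transcription note: the rendered source table is ambiguous
about the response column of the third bevacizumab patient (topotecan,
MR); that patient is encoded as a responder, the only assignment
consistent with the study's own aggregate MR row (9/17 responders in the
pooled table). `load_contingency()` serves the four historical 1990
extreme-drug-resistance tables (total, ovarian, single-agent,
combination) exactly as printed; one of them carries an internal
inconsistency (the single-agent MR cell prints 16% next to counts 9/79 =
11%) which the package resolves in favour of the counts.

## The synthetic-data generator

`sim_config()` fixes the study conditions for simulation: per-drug
Gaussian reference PCI distributions (the real reference populations are
proprietary/unpublished, so the defaults — mean 0.5, sd 0.2 for every
drug — are illustrative and labelled as such in generated metadata),
reference panels of 20 tumors per drug, arm sizes 16/3/33 matching the
bundled cohort, control count levels `cpm_neg = 2500`, `cpm_pos = 250`,
multiplicative lognormal noise with coefficient of variation 0.1 on every
count (counts are positive and their spread grows with signal; the factor
has unit median, and 0 disables noise), and class-conditional response
probabilities defaulting to the bundled cohort's pooled rates
$(p_{ER}, p_{MR}, p_{SR}) = (0,\ 9/17,\ 22/28)$, validated to be
non-decreasing — more in vitro sensitivity never lowers the response
probability.

`simulate_assay()` draws true inhibitions, synthesises the count triples
(`cpm_treated = cpm_neg − inh\cdot(cpm_neg − cpm_pos)` before noise,
floored at zero since counts cannot be negative), recovers PCI through
the same `assay_pci()` path real data would take and builds panels from
the recovered values, so panel estimation error is part of the simulation.
`simulate_cohort()` classifies fresh tumor draws against those panels,
scores combinations and draws Bernoulli responses. Everything is seeded:
the assay stage at `seed`, the cohort stage at `seed + 1`, so each stage
is bit-reproducible whether or not panels are reused.

`parameter_recovery_report()` closes the loop: it re-simulates cohorts,
re-estimates per-class response probabilities and the AUC, and reports
bias and CI coverage against the config truth. The truth AUC comes from
the closed form implemented in `expected_auc()` — class mix × response
probabilities → class distributions among responders and non-responders →
pairwise AUC with half-credit ties — with the class mix calibrated from
one large draw, because the induced mix depends on panel estimation and
count noise rather than only on $\Phi(-1)$ and $\Phi(0)$.

What the generator deliberately does **not** emulate: drug
concentration–response (concentrations are treated as fixed and
validated upstream), plate layout and well position effects, tumor-content
or viability QC, correlation between the two drugs of a combination
within a patient, and any latent confounder linking assay biology to
clinical response beyond the class-conditional Bernoulli model. Passing
the simulation-based tests therefore demonstrates the statistical
machinery is correct under the stated model, not that the assay is
clinically valid — the bundled-cohort analyses address the latter
question, on real recorded data.

## Numerical choices and problem sizes

* Class boundaries are compared with plain floating-point `>=`/`<`; no
  tolerance is injected, since PCI values are ratios of measured counts
  and exact boundary hits are measure-zero. The boundary conventions
  themselves are configurable as described above.
* Percent rounding is half-away-from-zero with a `1e-9` guard against
  binary representation of exact halves.
* Degenerate inputs fail loudly with typed conditions: zero-variance or
  single-value reference panels, empty cohorts or response groups, groups
  of size < 2 for the DeLong variance, `n = 0` proportions. The
  command-line wrapper maps validation errors to exit 2 and degenerate
  statistics to exit 3.
* Test problem sizes were chosen to keep the default suite fast while
  leaving no headroom for luck: 1,000 random contingencies against the
  brute-force AUC oracle, 10,000-replicate coverage checks per
  binomial setting, a 5,000-patient cohort for parameter recovery and
  150-replicate coverage runs for the recovery report.

## Limitations

* The evaluation treats the class as the unit of evidence; it has no
  patient-level covariates, no time-to-event structure and no comparison
  test between AUCs of different datasets — none are defined for this
  design.
* The exact intervals are conservative; for small classes (n = 3–7 here)
  the bounds are wide and rounding to whole percent is a presentation
  convention, not added precision.
* "Significance" statements for an AUC reduce to whether its CI contains
  0.5; no additional hypothesis test is performed.
* Reference panels are user-supplied or simulated; classification quality
  on new data depends entirely on how representative that reference
  population is for each drug.
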