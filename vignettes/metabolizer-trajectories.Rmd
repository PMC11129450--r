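---
title: "Metabolizer status and antidepressant treatment trajectories: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolizer status and antidepressant treatment trajectories: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxtraj)
```

## The scientific question

Cytochrome P450 enzymes CYP2D6 and CYP2C19 metabolize most antidepressants.
Genetic variation in these genes partitions patients into metabolizer
phenotypes — poor (PM), intermediate (IM), normal (NM) and ultrarapid (UM) —
and the pharmacogenomic hypothesis is that non-normal metabolizers, exposed
to too-high or too-low drug levels at standard doses, should more often
switch or discontinue their antidepressant, and perceive more side effects.
`pgxtraj` implements the full analysis chain needed to test this hypothesis
in a naturalistic longitudinal cohort: phenotype translation, substrate
classification, trajectory labelling, side-effect aggregation and the
statistical layer, plus a synthetic-cohort generator so the chain can be
exercised end to end when the clinical data themselves are access-restricted.

## Phenotype translation

Star-allele diplotypes are translated per gene.

**CYP2D6** uses a gene-dose (activity-score) scheme: a fully functional
allele (*1, *2) contributes 1, a reduced-function allele (*10, *17, *41)
0.5, an inactive allele (*3, *4, *6) 0. The diplotype's total dose is binned
into PM (0), IM (0.5–1) and NM (1.5–2.5). The bins are treated as closed
sets of reachable values: a dose that falls outside them (impossible under a
valid allele table) raises an error instead of being silently binned.

**CYP2C19** uses combination rules on functional classes: two
loss-of-function alleles (inactive or reduced) give PM, exactly one gives
IM, *17/*17 gives UM, and full/full or full/*17 gives NM under the DPWG
convention. The CPIC convention differs in exactly one cell: *1/*17 is UM.
Both conventions are implemented and the package's tests verify that the
difference is confined to full/increased diplotypes. Reduced-function
CYP2C19 alleles are accepted by the rule engine even though none of the
default alleles carries that label, so user-supplied tables remain
extensible.

Array-based genotyping cannot call the CYP2D6 *5 deletion or gene
duplications. The default `paper_compat` mode assigns such unidentifiable
alleles a *1 before translation — which inflates the apparent NM share and
makes UM undetectable, a caveat users should keep in mind — while `strict`
mode returns UNKNOWN instead. Records whose imputation posterior fails the
quality threshold are always UNKNOWN and are excluded from the collapsed
analysis groups.

## Substrate classes and subsamples

Antidepressants are keyed by 7-character ATC code and classified as
CYP2C19-only (5 drugs), CYP2D6-only (12), both (4) or neither. The table is
shipped as CSV data rather than code so it can be extended; drug names are
informational. A patient's analysis subsample (CYP2D6 and/or CYP2C19) is
fixed by the substrate class of their *index* drug — the single
antidepressant they used at the start of observation or first started during
it — even if they later switch class. Non-substrate drugs (e.g. tryptophan,
tranylcypromine) keep their users in the cohort but in no enzyme subsample.

## The 11-period trajectory model

Medication use is recorded over 11 ordered periods (intervals between
assessments alternating with current-use assessments, ending at the 9-year
follow-up). The classifier works from comparison pairs between successive
periods with antidepressant use. When two use-periods are interspersed by
drug-free periods, the gap-spanning comparison is preferred and the
consecutive comparisons inside the gap are neglected — this is what lets a
same-drug restart after a pause count as continuation rather than anything
else. Labels:

* **switched** — some comparison pair moves to a *disjoint* drug set. This
  reading treats switching as replacement: adding a second drug while
  keeping the first (augmentation) is not a switch. A switch back to the
  original drug after an intermediate different drug still counts, since a
  switch occurred somewhere.
* **discontinued** — use occurs within periods 1–4, no assessed period 5–11
  shows use, and at least one period beyond 4 was assessed.
* **not classifiable** — use confined to periods 1–4 with no assessment
  afterwards; continuation cannot be ruled out, so such patients are
  excluded from analysis rather than guessed.
* **maintained** — otherwise (use somewhere in periods 1–10, no switch).

Unassessed periods are skipped, never imputed as drug-free. Period 11
participates in switch comparisons and in the 5–11 emptiness test, but
eligibility for "maintained" rests on use within periods 1–10, mirroring how
the two definitions are worded. Switching takes precedence over
discontinuation because both other definitions require that no switch took
place.

## Side-effect aggregation

The 12-item binary side-effect checklist is collected per drug at the
interval periods 3, 5, 7 and 9. Items group into serotonergic (7 items),
cholinergic (dry mouth, constipation) and histaminergic (daytime sleepiness,
weight gain); dizziness counts only toward the total. Aggregation is
two-stage: mean count over a patient's qualifying drugs within a period,
then mean over the periods at which the patient has a qualifying response.
Missing periods are dropped from the denominator, not imputed as zero. The
questionnaire's printed response convention (0 = reported) is treated as a
transcription quirk; the canonical internal coding is 1 = reported, and the
reader accepts either via a flag, because a count of *perceived* side
effects must count reported items.

## Statistical layer

All models are crude (unadjusted): the published estimates equal the raw
cross-products, so no covariates are modelled.

* **Odds ratios** use the closed-form cross-product with Wald intervals
  `exp(log OR ± z · sqrt(1/a + 1/b + 1/c + 1/d))` and no continuity
  correction. Zero cells raise an explicit error; a Haldane–Anscombe +0.5
  correction is available behind a flag, never silently. Ten of the twelve
  published interval endpoints are reproduced exactly at two decimals from
  the published counts; two (5.13 and 0.70) sit one unit of the last printed
  digit away from the recomputed values (5.1248, 0.6946) under any z
  convention, which we attribute to display rounding in the original
  software chain.
* **Logistic regression** is fitted by iteratively reweighted least squares,
  converging when the largest score component falls below 1e-8 or the
  largest coefficient change below 1e-10, with a 50-iteration cap. Perfect
  separation is detected (diverging linear predictor with vanishing score)
  and raised as an error. On any non-degenerate 2×2 table the exponentiated
  coefficient equals the closed-form odds ratio; the test suite checks this
  equivalence to 1e-9 on hundreds of random tables and cross-checks
  coefficients against `stats::glm`.
* **Mann–Whitney U** is computed from midrank sums with the tie-corrected
  normal variance and no continuity correction by default (a continuity flag
  exists). An exact mode enumerates all group assignments of the pooled
  values, intended for total sizes up to 12, with the two-sided
  `p = 2 · min(P(U ≤ u), P(U ≥ u))` convention. A note on approximation
  quality: in the extreme tails at very small sizes the normal and exact
  p-values genuinely diverge — exhaustive enumeration shows worst-case
  differences of 0.23 at n₁ = n₂ = 2, shrinking monotonically to 0.07 at
  n₁ = n₂ = 6. The package therefore exposes the exact mode rather than
  pretending the approximation is uniformly tight; the suite asserts the
  (true) monotone-improvement property.
* **Post-hoc power** for two proportions uses Cohen's arcsine effect size
  `h = 2·asin(√p₂) − 2·asin(√p₁)` and the two-sided normal power
  `Φ(z − z₀.₉₇₅) + Φ(−z − z₀.₉₇₅)` with `z = |h| / sqrt(1/n₁ + 1/n₂)` — the
  "difference between two independent proportions" z-family. On the realized
  CYP2D6 switched comparison (223/575 vs 51/111) it gives 0.29.

## The synthetic cohort generator

The generator emulates the study conditions of a North-European
depression/anxiety cohort and is itself first-class, tested code.

* **Diplotypes** are drawn under Hardy–Weinberg equilibrium (independent
  alleles, random mating). Default allele frequencies are calibrated by
  minimizing the Hellinger distance between the Hardy–Weinberg-implied
  phenotype prevalences and the target prevalences (CYP2C19 PM 2.5%, IM
  20.9%, NM 70.7%, UM 5.9%; CYP2D6 PM 2.4%, IM 14.2%, NM 81.3% among known).
  The CYP2C19 targets are nearly Hardy–Weinberg-consistent and fit well
  (implied: 1.7/22.4/70.1/5.8%). The CYP2D6 targets are **not** jointly
  attainable under Hardy–Weinberg — matching PM = 2.4% forces IM ≥ 26% — a
  consequence of the *1-collapsing in the source genotyping; the calibration
  therefore compromises (implied: 0.8/16.9/82.2%), and the reduced-function
  class is pinned at 0.05 because an unconstrained fit drives it to an
  unrealistic zero without improving the fit. Within a functional class the
  mass is split across alleles in roughly European proportions; phenotypes
  depend only on class totals. CYP2D6 imputation fails with probability
  0.022.
* **Timelines**: the index drug is sampled with weights proportional to the
  drug distribution of the 928-patient reference cohort; the start period is
  1 with probability 0.6, otherwise uniform over 2–10 (the sources give no
  timing distribution; this is the package's one-off choice, with
  discontinuers drawing their start from 1–4 since their definition requires
  it). Labels are drawn from the configured maintained/switched/discontinued
  mixture (default 52/35/13%); switch and stop periods are uniform over the
  eligible range, and 30% of switches include a drug-free gap before the new
  drug so that gap-spanning comparisons are exercised. Group-specific
  effects tilt the switch and discontinue odds of collapsed phenotype groups
  by a configured log odds ratio.
* **Side effects and reasons** are drawn independently: items Bernoulli with
  per-category probabilities (defaults 0.25/0.30/0.25/0.20 — moderate report
  rates with dry mouth commonest, a realistic ordering), reasons multinomial
  with default 40/25/35% symptom-free/ineffective/side-effects, matching the
  overall pattern of the reference reason table.

What the generator deliberately does **not** emulate: linkage between the
two loci, population structure, dose changes, informative (non-uniform)
visit missingness, augmentation regimens and phenoconversion by
co-medication. Passing round-trip tests therefore demonstrates the
pipeline's internal consistency under the stated sampling model, not
fidelity to every feature of real cohort data.

## Numerical and design choices

* Timelines use set semantics per period; classification is invariant to
  input row order (tested by permutation).
* Every selection step reports kept + excluded = input (flowchart
  conservation), and the run log records all counts.
* Reports round percentages to 1 decimal and odds ratios, intervals and
  power to 2 — the precision used for comparison — while returned objects
  keep full precision.
* Reason records are matched on the interval period (5, 7 or 9) and the
  prior drug, because the questionnaire asks about a discontinuation at the
  interval while the event is detected by comparison with the following
  assessment (6, 8 or 10). Records with no matching medication change are
  dropped with a warning.
* The parameter-recovery study in the test suite uses 300 replicates of
  n = 4000 cohorts for CI coverage under an injected log(2) effect and 300
  null replicates for type-I error; these sizes give Monte-Carlo standard
  errors small enough to resolve the 93% coverage and 5 ± 2% rejection
  bands.

## Known limitations

* The CYP2D6 synthetic prevalences cannot match the reference table exactly
  (see above); analyses that depend on the absolute PM share at the default
  settings should supply their own frequencies.
* The trajectory rules encode the textual definitions; any additional edge
  conventions that the source study's unpublished full genotype-to-status
  grid or schematic figures may contain are not represented.
* Only crude associations are implemented — no covariate adjustment,
  multiple-testing correction or time-to-event modelling.
* The exact Mann–Whitney mode enumerates `choose(n1+n2, n1)` assignments and
  is intended for n₁+n₂ ≤ 12.

## A worked example

```{r example, eval = FALSE}
co <- generate_cohort(cohort_config(n_patients = 928), seed = 1,
                      out_dir = "cohort")
res <- run_pipeline("cohort", output_dir = "report")
res$association
res$power
```
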