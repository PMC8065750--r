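---
title: "Methods: simulating and validating an ordinal stroke-severity instrument"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and validating an ordinal stroke-severity instrument}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aspos)
```

## The instrument and its scoring rules

ASPOS grades posterior circulation stroke severity with seven ordinal
items — Reactivity, Eyes, Pharynx, Strength, Balance, Ataxia, Sensory —
scored 0–3 (0–2 for Ataxia and Sensory), for a maximum total of 19. Three
scoring conventions matter and are encoded in `scale_core`:

* **Tie-break upward.** When several level descriptions apply, the higher
  score is recorded (`score_item()` takes the maximum of the applicable
  codes).
* **Non-assessable items are skipped, not pro-rated.** An item that cannot
  be examined for reasons unrelated to the stroke is simply not added to
  the total, mirroring NIHSS convention. The total therefore has a reduced
  attainable maximum for such patients; we deliberately do not rescale,
  because rescaling would change the meaning of the severity strata.
* **Severity strata.** Totals 0–2 are LOW, 3 is INTERMEDIATE, ≥4 is HIGH.
  A total of 0 was not observed in the original cohort (minimum 1), but the
  mapping must be total on 0–19; 0 belongs with the sub-threshold LOW
  group.

The instrument itself is data, not code: `write_scale_definition()` /
`read_scale_definition()` serialize it as one CSV record per level, so an
alternative instrument can be analysed by the same pipeline without any
code change.

## The generative model behind the synthetic cohort

The original validation study provides only marginal summaries (medians,
ranges, the per-item reliability table), not per-patient data. The
simulator therefore implements the *minimal* generative model able to
produce all the phenomena the validation pipeline must detect:

1. **Latent severity trait.** Each patient carries a trait
   $\theta \sim \text{Exponential}(\text{scale} = 0.75)$. An exponential
   trait is the simplest right-skewed choice matching a cohort in which
   two-thirds of patients score at most 2 of 19 points (severe strokes
   with consciousness disturbance were procedurally excluded from the
   study design the simulator emulates).
2. **Deterministic item thresholds.** Item $j$'s consensus score is the
   number of its ordered cutpoints exceeded by $a_j\theta$ (discrimination
   $a_j = 1$ by default). Determinism gives the model its key invariant —
   consensus scores are monotone in $\theta$ — and makes all inter-item
   correlation flow through the single trait, which is exactly the
   unidimensionality Cronbach's α is supposed to measure.
3. **An off-scale item.** With probability 0.9 a patient's "Eyes" score is
   drawn independently of $\theta$ (level probabilities 0.68/0.24/0.05/0.03).
   This reproduces the one anomaly the real item analysis shows: an
   item with near-zero discriminatory power whose removal *raises* α,
   while its inter-rater reliability stays excellent (raters agree on what
   they see; what they see is just weakly related to overall severity).
4. **Local rater noise.** Each of the three day-1 raters, and the 3-hour
   retest, records each item one level off the consensus (±1, clipped to
   the item range) with probability 0.004. The noise is local because the
   observed repeatability is extreme: total-score disagreements between
   raters never exceeded one point in the original study. The default rate
   was calibrated from the published coefficient of repeatability
   (CR ≈ 0.46): with 7 items and two raters, the variance of the
   total-score difference is ≈ 14 p, so p ≈ 0.46²/1.96²/14 ≈ 0.004. This
   also reproduces the reported ~5% of pairs outside the limits of
   agreement.
5. **Companion-scale links.** NIHSS, mRS, Barthel, GCS and IVBSS are
   linear functions of $\theta$ plus Gaussian noise, rounded to each
   scale's granularity (Barthel in steps of 5) and clipped to its range.
   Intercepts and slopes were calibrated once so that simulated medians
   match the published cohort (NIHSS 2, mRS 1, Barthel 90, GCS 15) and the
   NIHSS range reaches ≈ 1–17 at n = 126. The GCS link is deliberately
   weak-looking: its ceiling at 15 for most mild patients produces the
   moderate (≈ −0.5) rank correlation observed in practice, while the
   other scales correlate strongly.
6. **Recovery.** Day-90 companion scores re-apply the links to
   $0.6\,\theta$ with fresh noise: uniform multiplicative recovery, no
   mortality or dropout (none were reported).

The IVBSS comparator's total-score maximum is not fixed by the validation
study; it is a configurable parameter (`ivbss_max`, default 30).

**What the simulator does not emulate.** Real items are scored by
clinicians from overlapping symptom constellations, so real item residuals
are correlated beyond a single trait; real rater error is not symmetric
(raters systematically differ in thresholds); severity is not
unidimensional. Consequently, green tests show the *statistics* are
computed correctly and that the pipeline detects the structures the model
plants (an off-scale item, a given agreement level, monotone links); they
do not certify the instrument itself on real patients.

## Numerical conventions

These choices are where independent reimplementations usually diverge; all
are fixed and tested:

* **Sample (n−1) variances throughout.** Mixing denominators moves α in
  the third decimal.
* **Item-rest correlation** is Pearson on raw integer scores against the
  sum of the *other* six items (corrected item-total). The uncorrected
  version inflates r and would be the wrong quantity to test against the
  0.3 discriminatory-power criterion.
* **ICC form.** The reliability of interchangeable trained raters is
  ICC(2,1): two-way random effects, absolute agreement, single rater — the
  strictest common form. The consistency variant is available by flag. CIs
  use the McGraw–Wong F construction. When raters agree perfectly within
  every patient the residual mean square is zero and the F interval is
  undefined; the estimate is reported as 1.00 and flagged degenerate with
  no CI, matching how such rows are conventionally printed.
* **Weighted κ** defaults to quadratic weights (κ values then track the
  ICC closely, which is the pattern the published reliability table
  shows); linear weights by flag. The CI uses the Fleiss–Cohen–Everitt
  large-sample variance. Categories default to the observed score range;
  adding empty categories does not change κ.
* **Bland–Altman.** CR = 1.96·SD of differences (not the root-mean-square
  variant): the published CR and near-zero mean difference imply the
  half-width convention. Limit CIs use SE = SD·√(3/n); the CR CI uses the
  χ² interval for an SD, scaled by 1.96. The sign of differences follows
  the arbitrary rater-pair order and is documented as such.
* **Spearman** uses midranks and the t approximation on n − 2 df.
* **Mann–Whitney** uses exact enumeration over all labelings when both
  groups have ≤ 8 observations (valid under ties) and the tie-corrected
  normal approximation otherwise, *without* continuity correction so that
  the two-group Kruskal–Wallis H equals z² exactly.
* **Kruskal–Wallis** delegates to `stats::kruskal.test`; the fully tied
  case is reported as H = 0, p = 1 rather than NaN.
* **Odds ratio under separation.** The severity-threshold table typically
  contains a zero cell (no severe-NIHSS case among LOW patients), which
  makes plain logistic-regression maximum likelihood non-identifiable. The
  pipeline uses the Haldane–Anscombe corrected cross-product ratio with a
  Wald interval: deterministic, standard, and explicit about when the
  correction fired (`correction_applied`). On the published group counts
  (5/4 vs 0/86) this yields OR ≈ 211 with an appropriately enormous CI; a
  software-specific ML estimate under separation can print a different
  finite number, which is why the correction flag and the cells themselves
  are part of the result.

## Open design points and how they were resolved

* **Which rater feeds the item analysis** is not fixed by the study
  design; the pipeline defaults to the first randomly selected day-1 rater
  and exposes the choice (`rater` flag).
* **Inter-rater statistic**: the pooled three-rater ICC is computed (not
  an average of pairwise values); the reliability table reports weighted κ
  for the test–retest pair only, following the conventional layout.
* **All-items-non-assessable** assessments are treated as an error rather
  than a zero total.
* **Whether a run may silently continue past a degenerate statistic**: per-item
  reliability records an NA with a note (a cohort can legitimately contain
  an item that never varies), but pipeline stages themselves abort loudly
  with the stage name.

## Problem sizes used in the tests

Oracle-equivalence checks run on ≥20 seeded fixtures of 8–15 observations
per statistic against independent brute-force implementations (covariance
arithmetic, `aov()` mean squares, disagreement-form κ, pair-counting U,
full enumeration). Simulation-based properties use: 200 replicate cohorts
at n = 126 for the median calibration; 100 replicates at n = 2000 with 5%
rater disagreement for parameter recovery of the per-item ICC against its
closed generative form; single n = 2000 cohorts for the qualitative
pattern (all ICC > 0.9, Eyes item-rest r < 0.3, ρ(total, NIHSS) > 0.7);
and 10,000 simulated pairs for the ~5%-outside-limits property of the
Bland–Altman bands. These sizes keep Monte-Carlo error well below every
asserted margin while the whole suite runs in well under a minute of
simulation time.

## Known limitations

* The generator's consensus scores are deterministic in $\theta$; real
  data would add item-specific residual variation, which would lower α and
  item-rest correlations toward (and below) their published values.
  The defaults were calibrated to the published *margins*, not fitted to
  per-patient data, so cohort-level statistics fluctuate around plausible
  values rather than reproducing the published ones exactly.
* Rater noise is symmetric and independent across items and raters; no
  rater-specific bias is modelled (the agreement ICC would detect one, and
  a test covers that discriminating behaviour on constructed blocks).
* Only complete cohorts are simulated; non-assessable items are supported
  throughout the scoring and I/O layers but are not generated.
```{r session}
sessionInfo()
```
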