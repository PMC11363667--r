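---
title: "Validating SDB screening questionnaires in pregnancy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating SDB screening questionnaires in pregnancy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdbscreen)
```

## The problem

Sleep-disordered breathing (SDB) in late pregnancy is common, consequential
and under-diagnosed. The reference standard — polysomnography (PSG), summarised
here by the respiratory disturbance index (RDI, respiratory events per hour of
sleep) — cannot be applied at scale, so practice relies on screening
questionnaires. `sdbscreen` implements the evaluation of two such screens
against PSG in a pregnant cohort: the Berlin Questionnaire (BQ) and the Wilson
Optimized Model (WOM), scored from the mother's answers and, where available,
her bedpartner's answers about her.

SDB status is dichotomised as RDI ≥ t with t = 5 (at least mild) and t = 15
(moderate-to-severe). Both comparisons are **inclusive**: a mother with
RDI exactly 5.0 is a case at the mild threshold.

## Scoring models

### Berlin Questionnaire

The BQ has three symptom categories. Categories 1 (five snoring/apnea items)
and 2 (three sleepiness items) are positive when at least two of their items
are at a symptomatic level; category 3 is positive when the respondent reports
hypertension or has measured BMI > 30 kg/m². Overall high risk requires at
least two positive categories. Two encoding decisions matter:

* **Symptomatic levels are data, not code.** The per-item symptomatic levels
  sit in the exported table `bq_symptomatic`. The defaults mark the top two
  frequency levels (3–4 times a week or more), the top two volume levels
  (louder than talking), and the affirmative binary answers. A site using a
  different edition of the instrument edits the table.
* **Missing answers count as non-symptomatic**, including "do not know"
  snoring. This is the conservative reading — a symptom not reported is not
  counted — and it lets partially answered questionnaires be scored, which
  real cohorts require (non-snorers legitimately skip the snore-volume,
  snore-frequency and bothers-others items). A category whose items are *all*
  missing is an explicit error, never a silent zero.

### Wilson Optimized Model

The WOM is an additive score over three BQ items — been told you snore,
snoring volume, tiredness after sleep — plus an indicator for BMI > 32 kg/m²,
with one weight per item level. The instrument's published constraints are the
total range [2.2, 25.2] and the high-risk rule *score strictly greater than*
18.1 (18.1 itself is low risk; the boundary is tested at 18.1/18.2). The
per-level weights themselves were published only in the original instrument's
supplementary appendix; the package therefore treats them as configuration
(`wom_weights()` reads a plain `item.level = weight` file) and ships a
**synthetic placeholder** that satisfies every structural invariant — range
endpoints exact, weights monotone in level, all finite and non-negative — but
is not the canonical table. Every contingency-table result in the package is
independent of the weights; only the continuous-score analyses (ROC/AUC) see
them.

Load-time validation enforces: minimum level weights summing exactly to
`score_min`, maxima to `score_max` (tolerance 1e-8), and monotonicity, so a
mistranscribed table fails fast.

One scoring rule needed a decision the instrument leaves open: a mother who
answers "no" or "do not know" to snoring cannot rate her snoring volume, yet
such mothers must receive WOM scores (validation cohorts contain them). A
missing volume for a non-"yes" snorer therefore resolves to the minimum-risk
level; this is the only permitted resolution, it is controlled by an explicit
`nonsnorer_volume` argument (set `"error"` to forbid it), and any other
missing item raises an error naming the item. There is no other imputation
anywhere in the package.

The BMI > 32 indicator is additive, like the three items. Plausibility of BMI
is checked softly: values outside (10, 80) kg/m² warn but do not stop the
analysis; non-positive values are errors.

## Diagnostic evaluation

From a 2×2 of screen result against SDB status the package reports
sensitivity, specificity, PPV, NPV (percentages), LR+ = Se/(1−Sp) and percent
correct. All values are kept at full precision; rounding is applied only at
render time (percentages 1 dp, likelihood ratios and χ² statistics 2 dp),
matching how such tables are conventionally printed. Zero-denominator ratios
(e.g. LR+ at Sp = 100%) yield `NA` markers, never exceptions. Useful
identities are enforced by tests rather than assumed: percent correct equals
the prevalence-weighted mean of Se and Sp, and LR+ ≥ 1 exactly when
Se ≥ 100 − Sp.

`counts_from_metrics()` inverts published summaries back to integer cells:
tp = ⌊Se·n⁺/100 + ½⌋, tn likewise from Sp, complements for fn/fp, followed by
a round-trip check that the recomputed percentages agree with the inputs at
the printed precision (0.05-point tolerance). Published tables that are
internally inconsistent are refused rather than silently approximated. Ties
at .5 round half-up, so the inversion is deterministic.

Two comparison decisions are deliberate:

* **No continuity correction.** The Pearson χ²(1) on correct/incorrect
  counts is uncorrected. Recomputing the validation study's four printed
  comparison statistics from the reconstructed tables reproduces all four to
  two decimals only without Yates' correction, which pins down the (unstated)
  convention; the uncorrected statistic is therefore the default and the only
  one offered for 2×2 tables.
* **Independent-samples comparison by default.** Comparing two screens scored
  on the same mothers is formally a paired design, but the unpaired
  correct-fraction χ² is what validation papers conventionally report, and is
  the default (`compare_correct_fraction`). A McNemar test on per-subject
  correctness indicators (`mcnemar_correct`) is provided for analysts who
  want the paired answer; it needs the per-subject vectors, which a pair of
  confusion tables cannot supply.

Rater agreement is the raw percent agreement on the mother×partner risk
cross-tab (the headline statistic in this literature), with Cohen's κ as
supplementary output, not the lead.

## ROC analysis

`roc_points()` sweeps all distinct score values (ties grouped; a score equal
to the threshold classifies positive), anchored at (0,0) and (1,1);
`auc_trapezoid()` equals the tie-corrected Mann–Whitney probability
P(S⁺ > S⁻) + ½P(S⁺ = S⁻), an identity the tests verify by brute-force pair
enumeration. Confidence intervals use the DeLong placement-component variance
by default — the standard choice when the CI method is unstated — with
Hanley–McNeil behind a flag; intervals are clipped to [0, 1]. When a class
has a single observation the component variance is undefined and falls back
to the Bernoulli bound θ(1−θ), giving a deliberately wide interval instead of
a failure. The mother-versus-partner AUC comparison is DeLong's paired test
with the z statistic squared to a 1-df χ² scale, matching how such
comparisons are reported; the original study does not describe its method, so
no numerical equivalence with its printed statistic is claimed. BQ risk is
binary, so no ROC is attempted for it.

The published AUCs (0.73 mother / 0.69 partner at RDI ≥ 5) are **not**
reproducible without the raw scores and are not targets; the synthetic cohort
instead carries a soft check that study-sized draws usually yield a
mother-score AUC inside the published interval [0.62, 0.84] — reported by the
test, not asserted.

## The synthetic cohort generator

The generator's defaults encode the validation cohort's structure; they are
study conditions, chosen once:

| parameter | default | rationale |
|---|---|---|
| `n_mothers` | 96 | completed-questionnaire cohort size |
| `partner_fraction` | 81/96 | bedpartner response rate |
| `rdi_log_mu`, `rdi_log_sigma` | 1.459, 1.07 | log-normal matched to median 4.3 (exp μ) and IQR (2.2, 9.3); the two quartiles imply σ of 0.99 and 1.14, averaged. This independently yields P(RDI ≥ 5) ≈ 0.44, agreeing with the observed 43.8% prevalence — a cross-check, not a fit |
| `hdp_fraction` | 0.54 | hypertensive-disorder rate |
| `hdp_odds_multiplier` | 2 | HDP doubles the odds of SDB class membership; normotensive mothers get the compensating factor m^(−f/(1−f)) so the marginal stays at the log-normal tails |
| `bmi_mu`, `bmi_sigma` | 35.8, 6.3 | cohort BMI; truncated below at 15 kg/m² |
| `partner_flip_prob`, `partner_up_bias` | 0.45, 0.70 | calibrated so Wilson-model mother–partner agreement lands near 75% with partner-high/mother-low discordance dominating (≈ 17% vs ≈ 8%) and a partner high-risk rate near 38% against the mother's 29% |

RDI couples to the questionnaire only through the discrete severity class
(none / mild / moderate-severe): the class is drawn first (HDP-adjusted),
then RDI from the log-normal truncated to the class interval, so SDB status
always equals the threshold rule exactly and the marginal RDI distribution is
preserved. Items are conditionally independent given class.

The class-conditional item tables were calibrated by **exact enumeration**,
not simulation: `implied_screen_prob()` computes P(screen high | class) in
closed form from the tables, the weight file and the BMI tail probabilities.
The three class-conditional Wilson positive rates (≈ 0.17 / 0.33 / 0.67 for
none / mild / moderate-severe) are the unique three-point solution that
simultaneously reproduces the published Wilson sensitivity and specificity at
*both* RDI thresholds, given the class sizes; the Berlin rates
(≈ 0.63 / 0.78 / 0.93) are derived the same way. The parameter-recovery tests
then check that the simulated pipeline reproduces the enumerated values
within one percentage point on a 50,000-mother cohort.

What the generator does **not** emulate: night-to-night RDI variability,
laboratory-versus-home device differences, gestational-age trajectories,
within-subject correlation between symptoms beyond the class, and any joint
distribution of symptoms with *continuous* RDI. Passing calibration tests
therefore demonstrates that the pipeline is correct and well-calibrated under
the stated generative model — not that the screens would achieve these
operating characteristics in a new clinical cohort.

## Numerical and engineering choices

* Determinism: every sampling function accepts a seed and restores the
  caller's RNG state; `generate_cohort` is bit-identical for identical specs.
* Degenerate inputs: single-class outcomes raise a typed error in ROC code;
  empty confusion tables are errors; zero-marginal 2×2 tables are refused;
  n = 0 cohorts are valid empty tables.
* Cohort files are plain CSV with lowercase level tokens; validation collects
  per-row problems (bad token, unparseable RDI) with row numbers instead of
  aborting, and every exclusion is tallied so denominators stay explicit.
* Test problem sizes were chosen as the smallest that make the Monte-Carlo
  error negligible against each tolerance: 50,000 mothers for 1-point
  operating-characteristic recovery, 10⁵ draws for RDI quantile checks, 500
  replicates for CI coverage and test size.

## Known limitations

* The shipped WOM weight table is synthetic; continuous-score results (ROC,
  AUC) under it are structurally faithful but not numerically comparable to
  analyses run with the canonical appendix weights.
* The unpaired screen comparison ignores the within-mother pairing, which is
  anticonservative or conservative depending on the correlation of errors;
  the McNemar alternative exists but changes the question being asked.
* Reconstructed contingency tables inherit the printed precision of their
  sources (1 dp); the round-trip check bounds, but cannot eliminate, that
  quantisation.
* The mother-versus-partner comparison uses all mothers against the partnered
  subset, as validation reports conventionally do; restricting mothers to the
  partnered subset is a one-line change on the confusion tables if a strictly
  like-for-like contrast is wanted.
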