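---
title: "Scoring and validating a damage index for autoinflammatory diseases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and validating a damage index for autoinflammatory diseases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(addiscore)
```

## The instrument and its scoring model

The Autoinflammatory Disease Damage Index (ADDI) quantifies accumulated,
irreversible disease damage in the four main monogenic autoinflammatory
diseases — familial Mediterranean fever (FMF), cryopyrin-associated periodic
syndromes (CAPS), TNF-receptor-associated periodic syndrome (TRAPS) and
mevalonate kinase deficiency (MKD). It is an additive index: 18 damage items
grouped into 8 organ-system categories, each category capped, and the total
score the sum of the capped category subtotals:

$$\mathrm{ADDI} = \sum_{c=1}^{8} \min\Big(\mathrm{cap}_c,\; \sum_{i \in c} p_i\Big),
\qquad \mathrm{ADDI} \in [0, 27].$$

Item points $p_i$ are fixed (1–3 points) or graded by severity (e.g. renal
insufficiency: moderate 2 / severe 3). `canonical_addi()` builds this
instrument as data — categories, caps, items, grading levels and the verbatim
glossary criteria — and the identical definition ships as
`inst/extdata/addi_v1.yaml`. Scoring logic is entirely data-driven, so a
modified instrument (different caps, extra items) flows through the same
engine.

An item only scores when it is *damage*: a persistent or irreversible change
in structure or function, present for at least 6 months, arising after
disease onset and not attributable to ongoing disease activity. Damage that
lasted 6 months and then resolved still scores. `is_damage_eligible()`
applies this gate uniformly to every item before grading; therapy-related and
comorbid damage arising after disease onset is eligible, only
activity-attributed findings are excluded.

### Grading rules and their boundaries

Measured evidence is routed through glossary-faithful graders:

* **Renal insufficiency** — severe if GFR < 15 mL/min/1.73 m² or
  dialysis/transplantation; moderate if 15 ≤ GFR < 60. We read "between 15
  and 60" as the half-open interval $[15, 60)$ so that moderate and severe
  partition with no gap or overlap, and GFR = 60 is not insufficiency (the
  glossary defines insufficiency as GFR < 60).
* **Proteinuria** — strict inequalities exactly as written:
  protein:creatinine > 20 mg/mmol, or protein > 0.3 g/24 h, or
  albumin:creatinine > 15 mg/mmol. A 24-h excretion of exactly 0.3 g does
  not score.
* **Growth failure** — paediatric: at least two of {height < 3rd
  percentile/−2 SD, 6-month velocity < 3rd percentile/−2 SD, crossing ≥ 2
  centile lines}; adult (> 18 y): pathological short stature.
* **Hearing loss** — the aid/cochlear-implant requirement separates severe
  (2) from moderate (1).
* **Ocular involvement** — documented damage without visual impairment (1),
  with impairment (2), legal blindness (3).
* **Osteoporosis** — requires *both* reduced bone density and vertebral
  collapse/pathological fracture; low density alone never scores.

Elevated intracranial pressure, serosal scarring, CNS involvement and the
other purely clinical items carry no quantitative criteria in the glossary
and are assertion-only: a rater (or data file) asserts the grade label
directly. Asserted mode is also how the validation study itself worked;
measured mode exists so synthetic data can exercise every grader path.

Missing evidence scores 0 and is recorded as `"not_assessed"` — missing is
not the same as absent, but both contribute 0 points; the index has no
missing-data arithmetic. Applicability violations (a paediatric-only item on
an adult, amenorrhea on a male case) are hard errors rather than silent
zeros, so malformed data surfaces immediately.

One deliberately open point: the instrument stores no exclusion rule between
amyloidosis and proteinuria, so renal amyloidosis with proteinuria scores
both items; the category cap of 6 bounds the impact.

## The reliability model

In the validation design, cases are split into blocks and each block is
scored by its own disjoint set of raters ("observer nested within subject").
Raters are not crossed with cases, so two-way ICC models are unidentifiable;
the appropriate estimator is the one-way random-effects, single-measures
ICC(1), in which consistency and absolute agreement coincide:

$$\widehat{\mathrm{ICC}} = \frac{MS_B - MS_W}{MS_B + (k_0 - 1)\, MS_W},
\qquad k_0 = \frac{N - \sum_i k_i^2/N}{n-1},$$

with $MS_B$ the between-case mean square ($n-1$ df), $MS_W$ the within-case
mean square ($N-n$ df) and $k_0$ the effective ratings per case for
unbalanced groups (a 3-rater group next to 4-rater groups is handled through
$k_0$; nothing is imputed). The 95% CI comes from the F pivot
$F = MS_B/MS_W$ with quantiles $F_{\alpha/2}(n-1, N-n)$ and
$F_{\alpha/2}(N-n, n-1)$, mapped through the same ICC transform. Negative
estimates are reported as computed and never clipped — transparency over
cosmetics; a display layer may floor at 0 with an annotation.

Cases with a single rating are dropped (with a warning); if every score is
identical the ICC is undefined and the cell is reported not-estimable.

Redundancy screening uses Cronbach's alpha,
$\alpha = \frac{m}{m-1}\big(1 - \sum_i \sigma_i^2 / \sigma_T^2\big)$, plus
the pairwise Pearson interitem matrix, flagging pairs with $r > 0.7$. Both
are computed on per-case mean item scores (cases as the unit of analysis,
same minimum-3-raters filter as the construct analysis) to avoid
pseudo-replicating raters. Zero-variance items are excluded from both alpha
and the matrix with a warning.

Construct validity is assessed with Spearman rank correlations of per-case
means: the mean ADDI against the mean 10-point physician global assessment
(PGA) of damage (convergent) and of disease activity (discriminant).
Strength bands follow the conventional cutoffs (|rho| 0.1–0.3 weak, 0.3–0.5
moderate, > 0.5 strong). The default CI is the Fisher z interval with the
Spearman standard error $1.06/\sqrt{n-3}$ (deterministic); a percentile
bootstrap over case resamples is available behind a seed. p-values use the
two-sided t approximation and are descriptive only — no decision in the
pipeline depends on them, and no multiplicity adjustment is applied.

## What the synthetic studies emulate

`study_design()` defaults to the reference layout: 110 cases (29 CAPS, 27
TRAPS, 29 FMF, 25 MKD) in 11 blocks of 10 cases, 4 raters per block, and
every item represented as eligible damage in at least 4 cases (enforced by
an injection pass after sampling). Per-disease item prevalence profiles
(`default_prevalence()`) are invented for clinical plausibility — hearing
loss enriched in CAPS, amyloidosis and serosal scarring in FMF/TRAPS,
developmental items in MKD/CAPS — and make no claim to reproduce registry
epidemiology. About 60% of cases are paediatric; roughly half of gradeable
evidence is generated in measured form so every grader runs; 10% of drawn
damage is generated ineligible (short duration or activity-attributed) to
exercise the eligibility gate.

Rater disagreement is a misclassification model (`rater_model()`): a present
item is missed with probability `p_miss` (default 0.05), an absent item
falsely scored with `p_false` (0.02), a graded item shifts one level with
`p_grade_confusion` (0.10). The original study's raw per-item disagreement
rates are unpublished, so this model is a labelled stand-in, not an
empirical fit. Perturbed grades are re-scored through the same engine as
real cases, so caps and totals always stay consistent.

PGA-damage is the true total rescaled to 0–10 plus Gaussian noise, rounded
to the integer survey scale. Two defaults were derived once from published
summary statistics and then frozen: `pga_noise_sd = 0.5` makes the simulated
PGA-damage reliability match the reported ICC of about 0.75, and
`activity_coupling = 0.6` (the weight of true damage in the latent activity
variable, against a uniform disease-activity component) solves analytically
for the reported damage–activity Spearman of about 0.4. With these defaults
the simulator reproduces the reported pattern without further tuning:
overall ICC ≈ 0.78, rho(ADDI, PGA-damage) ≈ 0.90, rho(ADDI, PGA-activity)
≈ 0.36. One numerical subtlety: a zero-noise rater reports the exact
rescaled value (no rounding), so the noiseless limit reproduces the true
ordering exactly — integer rounding would otherwise tie distinct totals and
break the exact noiseless contract.

`calibrate_noise_to_icc()` scales the three misclassification probabilities
jointly by one multiplier (keeping the search one-dimensional and monotone)
and bisects until the Monte-Carlo mean ICC over 20 simulated studies is
within tolerance (default 0.02) of the target. All randomness flows from one
root seed through named substreams (case generation, allocation, ratings,
calibration), so each stage is independently reproducible.

What a green simulation test does **not** establish: that real experts
behave like the misclassification model, that the prevalence profiles match
any registry, or that the original study's numbers are reproduced — its raw
ratings are unpublished. The simulator establishes that the estimators
recover known ground truth under the stated design, nothing more.

## A worked run

```{r}
instr <- canonical_addi()
instrument_max_total(instr)

study <- simulate_study(study_design(seed = 42L), rater_model())
report <- run_validation(study$ratings, instr)
report$overall
report$construct$vs_pga_damage
report$construct$vs_pga_activity
```

## Known limitations

* The original expert ratings are not public, so numeric agreement with the
  published per-item ICC table cannot be checked; only the estimators and
  the instrument arithmetic are verifiable, plus qualitative recovery of
  the published correlation pattern.
* The original analysis was run in SPSS, which may compute a two-way model
  even under nesting; the one-way model implemented here is the one the
  nested design actually identifies.
* Per-disease ICCs are computed on total scores (per-item ICCs are computed
  over all diseases pooled); whether the original per-disease cells used
  totals only is not stated.
* The PGA-activity reliability of the simulator is higher than reported,
  because the latent activity of a case is fixed across raters; matching
  that ICC would require a second rater-level activity noise component that
  nothing downstream needs.
* The pilot's sample-size rule (pilot ICC 0.85 implying "at least 90
  cases") cites no formula and is out of scope.
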