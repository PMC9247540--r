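---
title: "Evaluating fluid-responsiveness predictors around a lung recruitment maneuver"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating fluid-responsiveness predictors around a lung recruitment maneuver}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

During surgery under mechanical ventilation, giving fluid helps only the
patients whose cardiac stroke volume (SV) actually rises in response — the
*fluid responders*, conventionally defined by an SV increase of at least
10% after a standardized volume expansion (VE; here 250 mL of crystalloid
over 10 minutes). Because the fluid challenge itself is the thing one wants
to avoid giving unnecessarily, a *preload test* is used instead: a lung
recruitment maneuver (LRM; continuous positive airway pressure of
30 cm H₂O for 30 s) transiently raises intrathoracic pressure and reduces
venous return, and the magnitude of the hemodynamic dip it provokes
predicts responsiveness. The peripheral perfusion index (PI), a pulse
oximetry quantity, tracks SV during such transient tests without requiring
an arterial line, which makes the *relative PI decrease during the LRM*
(ΔPI_LRM) an attractive non-invasive predictor.

`fluidroc` implements the complete diagnostic-evaluation chain for this
setting: relative-change statistics at four time points (T1/T2 bracket the
LRM, T3/T4 the VE), responder classification, empirical ROC analysis with
DeLong inference, Youden cutoff selection, exact diagnostic metrics, a
two-approach gray zone, trending concordance, and ROC sample-size
planning — plus a calibrated synthetic-cohort generator so that every stage
is testable although no patient-level dataset is publicly deposited.

## Change statistics and the responder rule

For quantities that *fall* during the LRM (PI, SV, CO, SBP, DBP, MAP, HR)
the change is expressed as a percent decrease,
`(x_T1 − x_T2)/x_T1 × 100`, so larger positive values mean a larger dip.
Respiratory-variation indices (PPV, SVV, PVI) *rise* during the maneuver
and use the increase convention `(x_T2 − x_T1)/x_T1 × 100`, as do all
changes across the VE. The responder rule is boundary-inclusive
(`ΔSV_VE ≥ 10%` is a responder) while the return-to-baseline check between
the two interventions is strict (`|deviation| < 10%` passes; exactly 10%
fails) — both read literally from their definitions. Group-level summary
changes are means of per-patient ratios, not ratios of group means; the two
differ materially for skewed quantities like ΔPPV_LRM, and the package
documents (and tests) the distinction.

## ROC, cutoff, and diagnostic metrics

The AUC is the Mann–Whitney pair statistic (ties count ½). Confidence
intervals and the paired comparison of two markers use DeLong's
structural-components variance; the source that motivated this package
names no CI method, and DeLong is the standard assumption-free choice.
Candidate cutoffs are midpoints between adjacent distinct observed values
plus ∓∞ sentinels, so each attainable (Sn, Sp) pair is evaluated once; the
Youden index J = Sn + Sp − 1 is maximized, ties broken toward higher
sensitivity (the smallest maximizing cutoff when higher scores indicate
responders).

At a cutoff, sensitivity, specificity and predictive values get exact
Clopper–Pearson intervals via the beta-quantile representation — this
choice reproduces, at one-decimal rounding, all five printed intervals of
the study the package re-implements, which is the strongest available
evidence about the original (unnamed) method. Likelihood ratios get the
standard log-method interval, e.g. for LR⁺:
`exp(ln LR⁺ ± z·√(1/tp − 1/(tp+fn) + 1/fp − 1/(fp+tn)))`. When a cell of
the 2×2 table is zero, a 0.5 continuity correction is applied to all four
cells *for the LR intervals only* (with a warning); point estimates are
never corrected, and an infinite LR⁺ at Sp = 1 is reported as such with an
open upper interval. Percent display uses one decimal, rounding half away
from zero.

## The gray zone

Two constructions are computed and the wider one reported (ties prefer the
triadic zone):

* **Bootstrap**: 1,000 whole-cohort resamples (non-stratified — the
  simplest reading; stratified resampling is available behind a flag), the
  Youden-best cutoff recomputed per replicate, and the 2.5th–97.5th
  percentile interval of those cutoffs taken as the zone. Replicates that
  draw a single class are redrawn, so exactly `n_boot` cutoffs enter the
  percentiles; the percentile interval (rather than BCa) matches the plain
  "95% CI" phrasing. Everything is deterministic given the seed.
* **Triadic**: the marker range is partitioned into rule-out /
  inconclusive / rule-in regions by a sensitivity floor and a specificity
  floor (0.90 each by default): the lower bound is the largest cutoff
  still achieving Sn ≥ 0.90, the upper bound the smallest cutoff achieving
  Sp ≥ 0.90. The floors apply to Sn/Sp (not NPV/PPV); the methods wording
  of the source sets "thresholds related to Sn < 90% and Sp < 90%", and
  that reading is implemented. If the bounds cross, the zone is empty and
  collapses to their midpoint.

Zone membership is the closed interval `lower ≤ score ≤ upper`, and the
three population fractions are exact counts over the analysis cohort.

## Sample-size planning

The ROC sample-size method uses the equal-variance binormal variance
function `V(A) = 0.0099·e^(−a²/2)·[(5a² + 8) + (a² + 8)/R]` with
`a = √2·Φ⁻¹(A)` and R negatives per positive (so
`V(0.5) = 0.0099·(8 + 8/R)` exactly). The positive-group size is
`(z_α√V(null) + z_power√V(alt))²/(ΔA)²`; the total `n_pos·(1+R)` is rounded
half-up *before* the group sizes are re-derived from the ratio. Sidedness
and rounding order are not stated by the source; a one-sided α (the
alternative is directional, AUC > 0.5) with this rounding order reproduces
the published 27 evaluable patients (12.28 positives × 2.222 = 27.3), and
`ceiling(27/0.85) = 32` after 15% dropout inflation. The two-sided variant
is available and documented to give a larger n.

## Comparison tests and trending

Before/after and between-group comparisons route between parametric and
rank tests by a Shapiro–Wilk gate at α = 0.05 (the source says only "as
appropriate"; the routing is recorded in every result so reports are
auditable). The four-quadrant trending concordance drops pairs whose two
changes both fall inside a central exclusion square (default half-width
10%, the conventional choice — the source never states its zone, so it is
configurable) and reports the percentage of remaining pairs agreeing in
sign. The published concordance rate pools "all interventions", so the
pipeline concatenates the LRM changes (as increases) with the VE changes
for PI and SV; without patient-level data this convention cannot be
verified, and both the pair set and the exclusion width are exposed as
parameters rather than guessed silently.

## The synthetic cohort: a stated world

The generator emulates a 32-patient perioperative cohort with a responder
prevalence of 0.406 and the published group-wise means/SDs for every
variable at T1, for the LRM changes, and for the VE changes. Design
choices, fixed once:

* **Marginals** are truncated normal (only mean ± SD are published):
  baselines on (0, ∞), LRM decreases on (−50, 100)%, LRM increases on
  (−90, 500)%, VE changes on (−50, 200)%, after-VE variation indices on
  (0, ∞). Parent parameters are *moment-matched* numerically so the
  truncated distribution reproduces the published moments exactly — for
  PI (mean 2.3, SD ≈ 2) this matters: the naive parent would shift the
  mean by ~+0.5 after truncation at zero.
* **Correlation**: only the (ΔPI_LRM, ΔSV_LRM) pair is explicitly
  correlated, through a Gaussian copula with within-group ρ = 0.35, chosen
  once so the pooled r² across groups is ≈ 0.16, the published strength of
  that association. All other variables are independent given group,
  **except** the three arterial pressures: SBP, DBP and MAP share one
  latent uniform per patient per stage (levels, LRM change, T3 drift, VE
  change). Independent pressure draws would violate the physiological
  ordering DBP ≤ MAP ≤ SBP for roughly a fifth of patients; comonotone
  draws plus a final clamp of MAP into [DBP, SBP] (touching ~10⁻⁴ of
  values) keep the invariant with negligible moment distortion.
* **Responder boundary**: responders' ΔSV_VE is drawn on [10, 200)% (they
  satisfy the definition by construction); non-responders are drawn with
  mean 0.26% and SD 4% *without* truncation at 10, and the label is then
  re-derived from the realized value, so boundary crossings (~0.7% of
  non-responders) are relabeled. The SD of 4% is a fixed realistic choice:
  non-responders cluster tightly near zero SV change, and it keeps label
  crossovers rare so group calibration stays clean.
* **Values without published SDs** (fixed once, from the before/after
  group means where available): ΔSVV_LRM means 71.8/52.5% with SD 60%;
  VE-change SDs 10% (non-responder SV: 4%); T4 drift means for
  PI/SBP/DBP/HR from the T3→T4 ratio of means with SD 10%; T3 baselines
  drift around T1 by a truncated normal(0, 4%) bounded at ±9.5%, strictly
  inside the <10% return rule.
* **Missingness**: the default 32-patient spec blanks SVV entirely for two
  random non-responders, mimicking the published N = 17 for that variable;
  PPV/SVV/PVI have no T3 measurement at all, matching the source's dashes.

What the generator does **not** emulate: beat-to-beat physiology or
heart–lung interaction, any cross-correlation beyond the two cases above
(none are published), measurement rounding of monitors, or informative
missingness. A green pipeline test on synthetic data therefore establishes
computational correctness and calibration of the analysis chain, not
clinical validity of the marker itself.

Determinism: one seeded stream in a documented draw order; the caller's
RNG state is saved and restored, and the drawn group is preserved in
`attr(cohort, "drawn_responder")` so calibration checks can separate the
generator's accuracy from the (intentional) label re-derivation at the 10%
boundary.

## Numerical conventions and degenerate inputs

Ties contribute ½ to the AUC; scores missing for a marker are dropped
pairwise per marker. Single-class labels, fewer than two subjects per
class (DeLong variance), all-excluded concordance pairs, and zero-trial
proportions raise informative errors; an all-tied marker yields AUC 0.5
and J = 0. CSV values are written with 17 significant digits so write/read
round trips are bit exact. The pipeline catches stage errors, records them
under `stage_errors`, and still emits the remaining stages.

## Interfaces

The package is an analysis library: the R functions (`generate_cohort`,
`run_pipeline`, `obuchowski_n`, `write_report`, ...) *are* the interface,
and `scripts/acceptance.R` shows the end-to-end invocation; no separate
shell tool is shipped. Machine-readable output is JSON via `write_report`,
with a plain-text rendering alongside.

## Known limitations

* The published cohort's patient-level data are not deposited, so printed
  quantities that depend on individual values (the empirical AUC 0.81, the
  40% Youden cutoff, the 35–60% gray zone, the 29.64% concordance rate)
  can only be checked *in distribution* against the calibrated generator,
  not reproduced exactly.
* The moment calibration reproduces first and second moments; higher
  moments of the real physiology are not constrained.
* The Obuchowski implementation covers a single AUC against a null value;
  comparing two correlated AUCs at the design stage is out of scope.
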