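---
title: "Methods: lateralization indices, synthetic cohorts and diagnostic evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lateralization indices, synthetic cohorts and diagnostic evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avsli)
```

This vignette is the package's own account of its science: the indices and
decision rules, the two synthetic-cohort generators and their calibration,
the ROC/likelihood-ratio machinery, and the numerical choices made where
the design was genuinely open.

## The measurement model

One AVS procedure yields a cortisol/aldosterone pair at four venous sites —
the lowest point of the IVC (`ivc_low`), the left and right adrenal veins
(`lt_adv`, `rt_adv`), and the *substitute right adrenal vein* (`s_rt_adv`),
an IVC sample one vertebral level above the right adrenal-vein confluence —
before and after an ACTH bolus. Cortisol is carried in ug/dL and
aldosterone in pg/mL by convention; every index is a ratio of ratios in
which the units cancel, so no conversion logic exists anywhere in the
package.

Indices are computed from a single phase. The package defaults to the
post-ACTH phase, because the selectivity criterion (SI ≥ 5) is defined for
stimulated sampling; the phase is an explicit argument of
`compute_index_set()` and `run_pipeline()` for sensitivity analyses.

## Decision rules and their boundaries

`subtype_conventional()` implements the two-vein rule (LI ≥ 4 lateralizes
to the dominant side, otherwise IHA) and `subtype_modified()` the tri-class
rule on the modified index. Three conventions are fixed here and tested as
invariants:

- **Inclusive boundaries, attached to the abnormal class.** SI ≥ 5 and
  LI ≥ 4 are inclusive; by symmetry the modified-LI cutoffs are taken as
  mLI ≤ 0.7 (right APA) and mLI ≥ 2.2 (left APA). The three bands
  partition the positive axis, so every finite positive index receives
  exactly one label.
- **Ties.** Equal adrenal-vein A/C ratios give LI = 1 and side `"tie"`;
  since the unilateral cutoff exceeds 1, a tie can never lateralize.
- **Default cutoff pair 0.7/2.2.** Two printed sources for the modified-LI
  cutoffs exist in the literature this analysis follows (0.7/2.2 and
  0.3/3.1); the pair reported alongside the full sensitivity/specificity
  table is used as the default, and `avs_thresholds()` accepts either.

`adjudicate()` dispatches on right-vein selectivity only: a selective right
vein routes to the conventional rule, a failed one to the modified rule
(recorded as `rule = "fallback"`). Perturbation tests verify each branch
ignores the other branch's index entirely.

The eligibility filter (`cohort_filter()`) applies the exclusion cascade in
a fixed order — incomplete right-vein sampling, unoperated unilateral
diagnoses, post-operative ARR ≥ 200, post-operative blood pressure not
normalized, lost follow-up — attributing each excluded patient to the
*first* failing reason. The source protocol does not state that its
exclusion counts are mutually exclusive; first-match attribution is the
choice that makes the tally well defined, and it preserves the accounting
identity `included + sum(tally) = input`.

## The mechanistic secretion/dilution generator

The generator extends the unit-secretion thought experiment — a normal
gland secretes 1 unit, a lesion 10 units, and the substitute right
adrenal-vein site detects the sum of both glands — into a steady-state
dilution model. For gland aldosterone fluxes $A_L, A_R$ and a common
cortisol flux $F_C$ per gland, site concentrations are

$$
\begin{aligned}
\text{ivc\_low}&: (P_C,\; P_A)\\
\text{lt\_adv}&: \left(P_C + \tfrac{F_C}{q_{adv}},\; P_A + \tfrac{A_L}{q_{adv}}\right)\\
\text{rt\_adv}&: \left(P_C + \tfrac{F_C}{q_{adv}},\; P_A + \tfrac{A_R}{q_{adv}}\right)\\
\text{s\_rt\_adv}&: \left(P_C + \tfrac{2F_C}{q_{ivc}},\; P_A + \tfrac{A_L + A_R}{q_{ivc}}\right)
\end{aligned}
$$

with $q_{adv}, q_{ivc}$ the effective dilution flows, $P_A, P_C$ the
peripheral background, ACTH multiplying the fluxes (aldosterone ×3,
cortisol ×2 by default — order-of-magnitude stimulation physiology; they
cancel in every cortisol-normalized index at zero noise, so these defaults
are inert for index-level results), and independent multiplicative
lognormal noise of unit mean and coefficient of variation `noise_cv` on
each measured concentration. The mixing topology — the substitute site sees
*both* glands — is fixed, not a parameter: it is the anatomical fact the
modified index exploits.

Useful exact limits, all frozen into tests:

- zero noise and zero background with equal gland cortisol gives
  $\mathrm{mLI} = 2A_L/(A_L + A_R)$, the cortisol-normalized analogue of
  the toy model (0.18, 1.0, 1.82 for the three subtypes), independent of
  both flows;
- all indices are invariant under a common rescaling of fluxes and
  backgrounds (the "hormone unit" is arbitrary);
- the lognormal noise multiplies the modified LI by a four-factor
  lognormal, inflating its mean by exactly $(1+cv^2)^2$ and giving every
  class the same coefficient of variation $\sqrt{(1+cv^2)^4 - 1}$
  (`predict_mli_moments()`).

Default parameters (`mechanistic_params()`): fluxes 1/10 units, cortisol
flux 10, $q_{adv} = 1$, $q_{ivc} = 10$, background 0.5/0.5, noise CV 0.25.
These put the baseline in a physiologically sensible regime — adrenal-vein
selectivity indices far above 5, substitute-site concentrations a few-fold
above background — and are the uncalibrated starting point, not a fit.

## Calibration to the reference class moments

`calibrate_mechanistic()` fits $q_{adv}, q_{ivc}, P_A, P_C$ (Nelder–Mead on
the log scale) and the noise CV so that the class-wise modified-LI *means*
match a target table, by default the reference cohort moments
(`default_cohort_moments()`). Two structural facts shape the design:

- The objective is evaluated on the closed-form predicted moments, so the
  search is deterministic; a seeded Monte-Carlo cohort (40 000 draws per
  class by default) then verifies the fit.
- Because the noise inflation factor is common to all classes, it is
  profiled out by a one-dimensional search, bounded by `noise_cv_max`
  (default 0.8). The bound keeps the fitted measurement noise in a
  plausible biological range and prevents a degenerate solution in which
  the optimizer explains the target means almost entirely by heavy-tailed
  noise, where Monte-Carlo means converge hopelessly slowly.

The topology bounds what is achievable: with the substitute site detecting
$A_L + A_R$, the ratio of the left-APA to IHA zero-noise means is at most
$20/11 \approx 1.82$, below the target ratio $3.46/1.52 \approx 2.28$. The
minimax relative error on the three class means therefore has a floor near
11%, which the optimizer reaches; the 15% default tolerance is met, with
the residuals split across classes rather than concentrated in one.
Matching the three class *SDs* simultaneously is impossible under a single
shared noise CV (the targets' SD/mean ratios are 1.03, 0.57 and 0.73, and
the model forces them equal), so the tolerance check applies to means and
SD residuals are reported as diagnostics. An infeasible target — e.g. a
left-APA mean below the right-APA mean, which no parameter setting can
produce — yields a calibration-failure report (`success = FALSE`) carrying
the best residuals found.

## The distributional generator

`draw_cohort(mode = "distributional")` bypasses the mechanism and draws
index scores directly from per-class lognormals moment-matched
(`lognormal_from_moments()`: $\sigma^2 = \log(1 + (s/m)^2)$,
$\mu = \log m - \sigma^2/2$) to the reference class moments. Lognormals are
the natural family here: the indices are positive, right-skewed products
of ratios. This mode is used wherever the analysis needs the *score
distributions* rather than the measurement mechanism — notably AUC
estimation, where 20 000/30 000/60 000 draws at the study's 8:12:24 class
proportions pin the one-vs-rest rank AUC to about three decimals and agree
with the closed-form binormal value
$\Phi\!\left(\frac{\mu_1 - \mu_0}{\sqrt{\sigma_1^2 + \sigma_0^2}}\right)$
mixed over the rest-classes.

What the generators emulate — class-conditional index distributions, the
selectivity mechanism, dilution, measurement noise, the cohort's class
balance — and what they do not: catheter-position error beyond a binary
selectivity flag, ACTH pharmacokinetics, correlation between a patient's
pre- and post-ACTH noise, CT findings, or any treatment feedback. Passing
tests therefore demonstrate that the *analysis machinery* is correct under
the stated statistical structure, not that real cohorts follow that
structure.

## ROC, AUC and threshold selection

`roc_curve()` places candidate thresholds at every distinct observed score
(no midpoint interpolation — reproducible without tie-breaking on
unobserved values), groups ties, and adds the strict endpoint; thresholding
is inclusive to match the SI/LI boundary conventions. `auc_rank()` is the
midrank Mann–Whitney statistic and equals the trapezoidal area under the
curve exactly, instance by instance (a frozen property test).

`best_threshold_by_lr()` maximizes the empirical positive likelihood ratio
over points with specificity < 1 and sensitivity > 0. Perfect-specificity
points carry an infinite empirical LR and are excluded rather than
continuity-corrected, keeping the reported statistic exactly
sens/(1 − spec); ties break toward higher sensitivity, then toward the
less extreme threshold. One consequence, visible in the analysis scripts:
on near-continuous population-scale cohorts the empirical LR spikes at
extreme cutpoints that exclude all but one control, so LR-maximizing
cutoffs are a study-scale (n ≈ 44) procedure, while AUC is the
population-scale summary.

One-vs-rest framing is used for the per-class ROC of the modified index
(right APA vs both other classes, left APA vs both), with direction
`lower_is_positive` for right APA — its class sits in the low tail — and
`higher_is_positive` for left APA; the conventional index is evaluated for
unilateral-vs-idiopathic, where one-vs-rest coincides with the UAPA-vs-IHA
comparison.

## The rank-sum test

`rank_sum_test()` computes the midrank U statistic. For combined
$n \le 12$ the two-sided p-value is exact, by enumeration of all
$\binom{N}{n_A}$ group assignments. Above that it uses a moderated normal
approximation: the tie-corrected, continuity-corrected standardized
statistic evaluated as the *average* of the Gaussian tail and the
Student-t tail with $N-2$ degrees of freedom (Iman's approximation). The
moderation matters: against exact enumeration at combined $n = 12$, the
plain normal tail is off by up to ~0.016 in p while the moderated form
stays within ~0.005; below combined $n \approx 10$ no continuous
approximation can track the exact p uniformly (at 3-vs-3 the exact
two-sided p-values step in increments of 0.1), which is precisely why the
exact path is the default there.

## Numerical choices and degenerate inputs

- Errors are classed conditions (`avs_invalid_measurement`,
  `avs_incomplete_sampling`, `avs_parse_error`, ...) naming the offending
  field, site or row, so pipelines can distinguish data problems from
  usage errors.
- All stochastic operations take explicit seeds and restore the caller's
  RNG state; identical seeds give byte-identical serialized cohorts and
  reports.
- LR ties in `best_threshold_by_lr()` are compared with a $10^{-9}$
  relative tolerance to absorb floating-point noise in sens/(1 − spec).
- Degenerate ROC inputs (single-class labels) and empty rank-sum groups
  raise errors rather than returning NaN; an all-tied score yields the
  chance diagonal and AUC exactly 0.5.

## Problem sizes

The test suite and the acceptance script are sized so the whole battery
runs in well under the package's own CI budget on one CPU: 110 000
distributional draws for AUC estimation, 40 000 draws per class for
calibration verification, 1 000 random instances for the AUC/trapezoid
identity, 300 instances for the approximation-vs-exact rank-sum check, and
exhaustive pair enumeration only at $n \le 8$. These sizes were chosen once
as the points where Monte-Carlo error is comfortably below the tolerances
being checked.

## Known limitations

- The mechanistic model cannot reproduce the reference class-mean ratios
  exactly (the 11% floor above) nor the class-wise SDs under a shared
  noise CV; it is a validation instrument, not an estimate of physiology.
  Its calibrated dilution and background values are artifact constructs.
- The modified-index thresholds are calibration-dependent; the package
  ships both published pairs but takes no position on which generalizes.
- Specificity for the per-class tasks is defined against the pooled
  remaining classes; against IHA alone the numbers would differ.
- No confidence intervals on AUC are produced, and no DeLong comparisons:
  the analysis evaluates point performance under the stated conditions.
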