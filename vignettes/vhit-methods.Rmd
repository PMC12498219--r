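---
title: "Methods: vHIT signal analysis and the cohort association pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vHIT signal analysis and the cohort association pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vhitr)
```

## What the package computes

The video head-impulse test (vHIT) measures the vestibulo-ocular reflex
(VOR): during a brief, passive, high-acceleration head rotation in the plane
of one semicircular canal, a healthy VOR drives the eyes opposite to the head
at nearly equal speed, so the gain — eye velocity over head velocity — is
close to 1. `vhitr` implements the full analysis chain for such recordings:

1. **Trial QC** (`qc_trial()`, `select_valid_trials()`): trials are analysed
   only when peak head acceleration *strictly exceeds* 2500 deg/s² for the
   horizontal canals (HC) and 1500 deg/s² for the vertical canals (AC/PC);
   blink artifacts and per-direction gain outliers are removed, and a
   direction is usable only with at least 10 valid impulses.
2. **VOR gain** (`window_gain()`, `auc_gain()`): the primary per-trial gain
   is the eye/head ratio of mean velocities over the 40-ms window centred at
   peak head acceleration; an area-under-the-curve ratio over the impulse
   support is computed alongside.
3. **Catch-up saccades** (`detect_saccades()`, `is_reversed()`): corrective
   saccades are detected in the slow-phase-removed eye velocity; a *reversed*
   catch-up saccade is directed with (not against) the head rotation, exceeds
   60 deg/s, and lies on the saccadic main sequence.
4. **Classification** (`canal_status()`, `cohort_counts()`): per-canal mean
   gains are compared with normative mean ± 2 SD ranges (HC 0.86–1.20,
   AC 0.74–1.23, PC 0.72–1.29); Rey Complex Figure test (RCFT) copying and
   delayed-recall z-scores are abnormal below −2.0 (−1.0 in a sensitivity
   rule).
5. **Association statistics** (`run_primary_analysis()`): Spearman
   correlations of RCFT z-scores and MMSE with canal gains, and multivariable
   logistic regression with backward elimination for abnormal copying and
   abnormal delayed recall on a fixed candidate roster.

A synthetic-data module (`simulate_trial_set()`, `simulate_cohort()`)
generates impulse recordings and patient cohorts with programmable ground
truth so that every stage is testable without clinical data.

## The impulse model and its numerical treatment

The head impulse is modelled as a Gaussian velocity pulse
$v(t) = V\,e^{-(t-t_0)^2 / 2\sigma^2}$ with peak velocity $V$ (deg/s) and
width $\sigma$ (s). This shape was chosen because its peak acceleration has
the closed form $V/(\sigma\sqrt{e})$, giving the QC stage an analytic test
oracle: $V = 250$, $\sigma = 0.04$ yields 3790.8 deg/s², comfortably above
the HC threshold, while $V = 150$, $\sigma = 0.05$ yields 1819.6 deg/s²,
which clears only the vertical-canal threshold.

**Differentiation.** At the 120 Hz sampling rate of clinical devices a
realistic impulse rises for only 5–6 samples. A Savitzky–Golay (window 5,
order 2) derivative — the textbook choice for noisy traces — biases the peak
acceleration of such pulses down by 3–5%, and even a plain central difference
loses 1.5–2%, so neither can certify thresholds stated to 1%. The package
therefore differentiates a natural cubic interpolating spline analytically
and locates the peak on a 16× dense grid; on Gaussian pulses this agrees with
the closed form to about 0.01%. The eye trace carries the measurement noise
in this model (the head trace is driver-controlled), so no pre-smoothing is
applied before differentiation; a noisy head channel would warrant adding
one.

**Strictness at thresholds.** Acceptance requires peak acceleration strictly
above the canal-class threshold. The comparison uses a $10^{-9}$ relative
guard so that floating-point noise in the spline derivative (observed
~$10^{-14}$ relative) cannot promote an exactly-at-threshold trial.

## Gain estimators

The **window gain** is $|\overline{\dot e}| / |\overline{\dot h}|$ over the
40-ms window centred at the peak-acceleration sample. 40 ms at 120 Hz is 4.8
sample intervals; the package uses the nearest symmetric odd window, 5
samples (peak ± 2), so results are bit-reproducible. The window precedes
typical catch-up saccade latency, and saccade lobes are not excised from it;
when a reversed saccade overlaps the window this can inflate the gain, which
is why reversed-saccade flags are reported alongside.

The **AUC gain** integrates $|\dot e|$ and $|\dot h|$ by the trapezoidal rule
over the impulse support (the contiguous run where $|\dot h|$ is at least 10%
of its peak). Detected saccade lobes are excised from the eye trace by linear
interpolation across the lobe before integration, so catch-up saccades do not
inflate the slow-phase area. On noiseless saccade-free fixtures both
estimators return the programmed gain to better than $10^{-9}$ and agree with
each other to $10^{-6}$ across a grid of $(V, \sigma, \text{gain})$.

The window gain is the primary statistic: per-direction means (≥ 10 trials)
feed the normative classification, and the side-averaged value per canal
class feeds the association models. Both side-level and side-averaged
summaries are emitted because cohort tables conventionally report both.

## Saccade detection and the main sequence

The compensatory slow phase is removed by adding `gain × head velocity` to
the eye velocity, using the trial's own window gain, which exposes covert
saccades superimposed on the compensatory response. Because a small saccade
spans only 2–4 samples at 120 Hz — the sampled peak of a 1°, 90 deg/s lobe
can fall 30% below its true value at unlucky sampling phase — the residual is
reconstructed on a 16× dense grid with a natural cubic spline before
thresholding at 60 deg/s. Single-signed supra-threshold runs are candidate
lobes; equal-signed runs separated by less than 2 samples are merged
(noise-split lobes), and lobe boundaries are extended to where the residual
falls below max(5 deg/s, 5% of the lobe peak) before the amplitude integral
is taken.

A detected event is a **reversed catch-up saccade** when (i) its direction is
with the head rotation, (ii) its peak velocity exceeds 60 deg/s, and (iii) it
lies on the saccadic main sequence
$v_{peak} = v_{max}(1 - e^{-A/c})$, within a 25% tolerance. The device
cutoff used clinically is not published; the defaults $v_{max} = 500$ deg/s
and $c = 5$° are standard human values, are pinned by tests, and are fully
configurable. The main-sequence test is what separates saccades from
artifacts: a 400 deg/s event of 0.5° amplitude (predicted peak ≈ 47.6 deg/s)
is an artifact, not a reversed saccade.

**Blink rule.** The simulated blink is a biphasic ±400 deg/s transient of
~80 ms. A rule of the form "any sample above 350 deg/s outside saccade lobes"
cannot flag it, because each blink half-lobe in isolation satisfies the main
sequence and so *is* a detected lobe. The QC blink detector therefore adds a
biphasic criterion — opposite-signed excursions beyond the 350 deg/s cutoff
within 100 ms — alongside the outside-lobe rule. Legitimate catch-up saccades
(60–300 deg/s) never reach the cutoff.

**Outlier rule.** The exclusion of "outlier" trials is implemented at the
trial-set level: a trial whose window gain falls outside median ± 3 MAD of
its direction's accepted gains is rejected (configurable; skipped when the
MAD is zero, and when fewer than 3 gains are available). At n ≈ 10 the MAD is
itself noisy, so the rule false-flags a few percent of clean noisy trials;
this is the documented price of a robust rule at clinical trial counts, and
count-sensitive tests use noiseless sets where the rule is provably inert.

## Normative classification and pattern counts

Canal status is `decreased` strictly below, `overestimated` strictly above,
and `normal` on or within the normative bounds (inclusive bounds: the ranges
define "outside the normal range" as abnormal). The published control ranges
are shipped as frozen constants; `build_normative_range()` derives
mean ± 2 SD (sample SD) ranges from new control cohorts.

`cohort_counts()` aggregates per-patient patterns: any-decreased,
any-overestimated (a patient may be both), all-normal, and per canal class
the right-only / left-only / both-sides breakdown. Percentages are rounded
half away from zero, which reproduces all four published percentages
(7%, 10%, 36%, 46%) from their counts. Two identities are enforced by
property tests: subgroup partition (right_only + left_only + both = total)
and the macro-state account
(all_normal + any_decreased + any_overestimated − both_categories = n).

## The statistical layer

Rank statistics, the exact contingency test, and penalised logistic
regression are implemented in the package, with base-R routines used only as
independent oracles in the tests:

- **Spearman**: Pearson correlation of midranks; two-sided p from the
  $t = r\sqrt{(n-2)/(1-r^2)}$ approximation (handles ties naturally).
- **Mann–Whitney**: midrank U; exact null distribution (no ties, both groups
  ≤ 20) or the tie-corrected normal approximation with continuity
  correction.
- **2×2 tables**: Fisher's exact test (two-sided by the point-probability
  rule) whenever an expected cell is below 5, else 1-df chi-square without
  continuity correction (configurable).
- **Logistic regression**: Newton scoring to $|\text{score}| < 10^{-8}$;
  Wald CIs as $e^{\beta \pm 1.96\,SE}$. Firth's Jeffreys-prior penalty is
  available because a copy-abnormality model with ~11 events in ~151
  patients is near-separated (the plain fit warns and the reported ORs can
  collapse toward 0.001 with very wide CIs, as in the motivating analysis);
  the default remains plain MLE to mirror common clinical practice.
- **Backward elimination**: iteratively drops the largest Wald p above
  `alpha_remove` and refits. The default stay criterion is 0.10, not 0.05:
  published final models of this kind retain covariates with p ≈ 0.08,
  which is consistent with the common software default of 0.10 but not with
  0.05. No multiple-testing correction is applied (matching the analysis
  being emulated); reports note this.

`run_primary_analysis()` fixes the candidate roster (age, sex, disease
duration, MDS-UPDRS-III, kinetic tremor, orthostatic hypotension, schooling,
MMSE, SCOPA-PC, depression, anxiety, cadence, HC/AC/PC side-averaged gains)
and runs the copy and recall models, the 3×3 Spearman correlation table, and
two sensitivity re-analyses: the lenient z < −1.0 threshold, and
decreased-gain indicators (any side below the normative range) replacing the
continuous gains.

## The synthetic cohort: what it emulates, and what it does not

`simulate_cohort()` draws one row per patient with the structure of a
de-novo Parkinson's disease cohort: age 68 ± 9 years, 49% female, per-canal
gains centred at the observed medians (SDs back-calculated from IQRs,
≈ 0.12–0.19), MMSE as 30 − Poisson(2) (median 28, IQR 27–29), disease
duration and motor scores as rounded log-normals matched to the published
medians/IQRs, staging sampled from the published distribution, and
comorbidity flags at the published prevalences. Where the sources give no
value (e.g. schooling ≈ 12 ± 5 years, gait parameters), a single realistic
choice was made and is fixed.

The programmable associations are the point of the generator:

- P(abnormal copying) follows
  $\text{logit}\,p = \beta_0 + \beta_1 \cdot \text{HC gain}$ with defaults
  $\beta_1 = -6$ and $\beta_0 = 3.59$;
- P(abnormal recall) follows a logistic model on (MMSE, age, male sex,
  schooling) with the published point estimates as default coefficients and
  intercept −6.05.

Both intercepts were calibrated by numerically solving
$E[p(x)] = 11/151$ and $15/151$ under the default covariate distributions,
so the marginal abnormality rates match the published 7% and 10%
prevalences. z-scores are drawn *consistently with the drawn labels* —
truncated normals below −2 for abnormal patients (copy −2.7 ± 0.5, matching
the published group mean) and above −2 otherwise — rather than from a model
of the RCFT instrument itself.

What the generator does **not** emulate: eye-tracker physics (pupil loss,
goggle slippage), correlated gain errors across canals within a patient,
missing data, and any real link between motor severity and vestibular
function. A green parameter-recovery test therefore establishes that the
pipeline recovers programmed structure from data of this shape — not that
the clinical effect estimates themselves are reproduced, which is impossible
without the original recordings.

## Recovery testing and the stay criterion

The acceptance suite's recovery test simulates 20 cohorts of n = 5000 with a
true HC-gain effect on copying (slope −6) and a recall model generated from
MMSE/age/sex only, and requires that backward selection retain HC gain (OR
< 1) in the copy model and retain *no* canal gain in the recall model in at
least 18/20 seeds. Under the default stay criterion of 0.10, each of the
three null canal gains is retained with probability ≈ α, so all three are
absent with probability ≈ 0.9³ ≈ 0.73 per seed and an 18/20 success rate is
unreachable *by design of the selection rule, not by any defect in the
fit*. The recovery test therefore runs at `alpha_remove = 0.01`: at n = 5000
the true effect has p ≈ 10⁻²⁰, so the stringent criterion costs no power
while keeping false retention near 3% per model. The 0.10 default is a
clinical-reporting choice, not a recovery-testing one, and both are exposed
as parameters.

## Determinism, tolerances, degenerate inputs

- Every stochastic routine takes an explicit seed; the pipeline stamps each
  artifact with the config hash and seed, and identical configs produce
  byte-identical JSON/CSV artifacts (no timestamps are written).
- Gain round-trips are asserted at $10^{-9}$ (noiseless), estimator
  agreement at $10^{-6}$, peak acceleration against the closed form at 1%
  (actual ~0.01%).
- Degenerate inputs error early with informative messages: all-zero head
  traces and empty impulse supports (undefined gain), constant vectors
  (undefined rank correlation), all-zero contingency tables, single-class
  outcomes, and sub-window traces.
- A zero-MAD trial set (identical gains) skips outlier rejection; fewer than
  10 valid trials yields an *unavailable* summary rather than an error, and
  `canal_status()` maps missing gains to `unavailable`.

## Known limitations

- The 5-sample window is an approximation to 40 ms at 120 Hz (41.7 ms); at
  other sampling rates the window is still chosen as the nearest odd sample
  count, asymmetric rates are not special-cased.
- Saccades of sub-sample duration (main-sequence violators by construction)
  cannot be reconstructed faithfully at 120 Hz; they are detected as spikes
  and correctly rejected by the main-sequence screen, but their reported
  amplitudes are interpolation artifacts.
- The AUC gain's saccade excision interpolates linearly across lobes, which
  slightly under-curves the slow phase beneath long saccades.
- Firth penalisation uses the leverage form of the modified score; profile
  penalised-likelihood CIs are not implemented (Wald CIs are reported even
  for Firth fits).
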