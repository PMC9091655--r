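---
title: "Methods: deceleration capacity, HRV, and incremental prognostic value"
author: "dcgrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deceleration capacity, HRV, and incremental prognostic value}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcgrace)
```

## The scientific problem

After an acute coronary syndrome (ACS), clinicians stratify patients with
the postdischarge GRACE score, a points system built from age, hemodynamics,
renal function, biomarkers and in-hospital course.  The GRACE score carries
no information about cardiac autonomic function, yet depressed vagal
modulation of heart rate is an established marker of poor prognosis.
Deceleration capacity (DC), computed from an ordinary 24-h Holter recording,
summarises deceleration-related vagal modulation in a single number in
milliseconds.  `dcgrace` implements the full analytic chain for asking: *does
adding DC (or a conventional HRV index such as LF/HF) to a GRACE-only risk
model measurably improve the prediction of major adverse cardiac events
(MACE: death or non-fatal myocardial infarction)?*

Because no patient-level dataset is distributed with recordings of this
kind, the package ships a synthetic cohort generator with known ground
truth; every stage of the pipeline is validated against it.

## Phase-rectified signal averaging and DC

PRSA extracts quasi-periodic structure from a noisy, non-stationary beat
series by averaging windows aligned on *anchors*.  For DC, the anchors are
decelerations: beats whose NN interval exceeds the preceding one.  An anchor
is rejected when the increase exceeds 5% of the preceding interval (the
canonical artifact bound, `max_relative_increase`, configurable), when
either beat sits next to a filter gap, or when the averaging window
`[i - L, i + L - 1]` (default `L = 2`) is incomplete or spans a gap.  With
`X(k)` the anchor-averaged interval at offset `k`,

$$\mathrm{DC} = \frac{X(0) + X(1) - X(-1) - X(-2)}{4}.$$

This signed Haar contrast is the package default (`formula_convention =
"signed"`).  An all-plus variant of the formula is sometimes seen in print;
on a stationary series it evaluates to roughly the *mean* NN interval
(hundreds of ms) rather than a modulation amplitude (0--10 ms), so it cannot
be the quantity reported clinically.  It is retained behind
`formula_convention = "as_printed"` for audits, and a test asserts the large
discrepancy between the two conventions.

Beats enter the NN series when labelled normal, inside 300--2000 ms, and
within 20% of the last accepted beat (sequential filter).  These bounds are
standard Holter practice; they are exposed as arguments because vendor
software rarely documents its exact rules.  Removed beats set a gap flag on
their successor; windows and successive-difference statistics never span a
gap, preserving phase coherence.  Risk stratification uses the established
cutpoints: low risk above 4.5 ms, intermediate risk in (2.5, 4.5], high risk
at or below 2.5 ms (`dc_risk_group()`), each boundary belonging to the
lower band.

## HRV panel

Time domain: SDNN (sample SD of all NN intervals), SDANN (SD of per-segment
mean NN over consecutive 5-min windows anchored at the recording start, the
incomplete tail dropped -- deterministic and order-independent), rMSSD and
pNN50 (successive differences, pairs across gaps excluded), and mean heart
rate defined as `60000 / mean(NN)` so that recording gaps do not bias it.

Frequency domain: the tachogram (interval value vs beat time) is unevenly
sampled, so band powers use the Lomb-Scargle periodogram directly, with no
resampling or interpolation.  The periodogram is evaluated from `1/span` to
the mean Nyquist frequency (oversampling factor 2) and normalised so that
the total gridded power equals the series variance; a band power is the
variance share inside the band, in ms².  This makes Parseval's relation
hold by construction: a pure sinusoid of amplitude $a$ inside a band yields
a band power of $a^2/2$, which the tests assert to 10%.  Band edges follow
the standard convention, LF 0.04--0.15 Hz and HF 0.15--0.40 Hz, with LF
half-open on the right so no grid frequency is counted twice.  A 24-h
LF/HF is reported as one number from a single long-record periodogram
(rather than averaging 5-min spectra) -- with the normalisation above the
two choices differ little for stationary series, and the single spectrum
needs no segmentation policy.  When HF power is exactly zero the LF/HF
ratio is reported as missing, never infinite.

## Outcome models

Logistic fits (`fit_logistic()`) use iteratively reweighted least squares
with step-halving, iterating until the relative log-likelihood change falls
below 1e-10 (at most 100 iterations); the per-iteration log-likelihood
trace is stored and is non-decreasing by construction.  Perfect separation
raises an error instead of returning a silently diverged fit.  The exact
log-likelihood and per-patient predicted probabilities are first-class
outputs because the enrichment statistics consume them.  Cox models,
Kaplan-Meier curves, the log-rank test and Harrell's concordance delegate
to the survival package (Efron tie handling by default, Breslow available);
hazard ratios carry Wald 95% intervals `exp(b ± 1.96 SE)`.

The baseline table compares each variable across DC groups.  Continuous
variables pass a per-group Shapiro-Wilk gate at alpha = 0.05: all groups
normal gives mean (SD) with one-way ANOVA, otherwise median (IQR) with
Kruskal-Wallis; the gate decision is recorded per variable.  Categorical
variables report counts (%) with *both* the Pearson chi-square and the
likelihood-ratio G statistic.  The dual report exists because the two
diverge materially on sparse tables (a zero cell can move the statistic by
several units), and published tables do not always say which variant they
used; reporting both makes every row auditable.  No multiple-testing
correction is applied (flagged in the report metadata).

## Incremental-value statistics

For a base score and an added marker, `model_enrichment()` fits the nested
logistic models and reports:

* **Likelihood-ratio test**: $\chi^2 = 2(\ell_{full} - \ell_{base})$,
  df = parameter difference.
* **AICc and Akaike weights**: $AICc = -2\ell + 2k + 2k(k+1)/(n-k-1)$;
  $\delta_i = AICc_i - \min AICc$; relative likelihood $e^{-\delta_i/2}$,
  normalised to Akaike weights.
* **Continuous NRI**: among events, the net fraction whose predicted risk
  rose; among non-events, the net fraction whose risk fell; total NRI is
  the sum.  Exact ties count as no movement but stay in the denominators.
  Components get the asymptotic binomial SE
  $\sqrt{(up+down)/n^2 - (up-down)^2/n^3}$, combined in quadrature, and a
  two-sided z-test.  The movement-count table is always emitted so the NRI
  is auditable from counts alone.
* **IDI**: the gain in discrimination slope (mean predicted risk in events
  minus non-events), computed both as the sum of the event and non-event
  components and as the slope difference; the implementation verifies the
  two agree to 1e-9 on every call.  SE is
  $\sqrt{var_e(d)/n_e + var_{ne}(d)/n_{ne}}$ with $d = p_{new} - p_{old}$.
* **ROC**: AUC as the tie-corrected Mann-Whitney statistic (equal to the
  trapezoidal ROC area; a test asserts the identity to 1e-10), SE by the
  DeLong placement decomposition (Hanley-McNeil behind a flag), the Youden
  operating point (`J = sens + spec - 1`, ties resolved to the lowest
  threshold), and -- when follow-up times are available -- Harrell's C, the
  survival-sided view of discrimination.  Both the binary AUC and Harrell's
  C appear in the report because they answer slightly different questions
  and published tables sometimes mix them.

Enrichment probabilities come from logistic fits on the binary MACE
outcome even though follow-up is time-to-event -- this mirrors how
reclassification analyses are typically run -- and Harrell's C supplies the
censoring-aware complement.  Significance for NRI and IDI uses asymptotic
z-tests; a percentile bootstrap could replace them but the asymptotic forms
hold their size in the regimes tested (below).

## The synthetic cohort generator

`generate_rr_series()` builds beat intervals on a nominal beat grid as
`base_rr(1 + circadian) + LF + HF + noise`: a 24-h circadian sinusoid
(amplitude 8% of base, slowest mid-recording), an LF oscillation (0.10 Hz,
8 ms), an HF (respiratory/vagal) oscillation (0.25 Hz, amplitude = the
vagal-tone dial), and Gaussian beat noise (5 ms).  With probability 0.003
per beat, a premature beat appears (interval scaled 0.6, labelled ectopic)
followed by a mild 1.15x compensatory pause; the pause survives the 20% NN
filter, so the fraction of beats removed tracks the injection rate.

`generate_cohort()` draws a latent vagal tone and the GRACE score from a
Gaussian copula (correlation -0.3; higher GRACE goes with lower tone),
maps tone to HF amplitude as `10 * exp(0.7 z)` ms with `z` truncated at
±3 SD (beyond that the implied amplitude swamps the 5% anchor bound), and
computes DC *through the package's own signal pipeline*.  The
pipeline-computed DC -- not the latent tone -- then enters a
proportional-hazards Weibull model (shape 1.2, scale 320 months, hazard
multiplier `exp(log(1.020)(GRACE - mean) + log(0.885)(DC - mean))`), with
administrative censoring at 60 months and events split 9:32 between death
and non-fatal infarction.  Closing the loop through the signal stage means
parameter-recovery tests exercise the whole chain, not just the survival
model.  The calibration gives DC spread over roughly 2--10 ms across the
2.5/4.5 ms cutpoints and an event rate near 13--15%.

Per-patient recordings default to 15 minutes (`rr_duration = 900`) in the
cohort generator: the shortest record with two complete SDANN segments and
a stable anchor count (several hundred anchors), which keeps
multi-replicate simulation studies tractable; single-recording analyses use
the 24-h default of `rr_gen_params()`.  What the generator does **not**
emulate: real respiratory frequency wander, atrial fibrillation or other
non-sinus rhythm (excluded populations), circadian ectopy clustering, and
measurement error in beat detection.  Passing tests therefore demonstrate
correctness of the estimators and the internal consistency of the chain,
not robustness to every pathology of clinical Holter data.

## Numerical choices and degenerate inputs

* Convergence: logistic IRLS at relative log-likelihood 1e-10; Cox at the
  survival package defaults.
* Ties: midranks throughout (AUC, rank tests); reclassification ties count
  as no movement; Youden ties resolve to the lowest threshold; Efron
  approximation for Cox event-time ties.
* Degenerate inputs are flagged, not silently patched: constant risk score
  gives AUC 0.5 with a `degenerate` flag; all-tie reclassification reports
  NRI 0 with SE 0 and a flag; a constant baseline variable is reported with
  SD 0 and no test; zero HF power yields a missing LF/HF.
* An empty anchor set is an error object carrying `anchor_count = 0`, so
  callers can distinguish "no decelerations" from I/O failures.

## Problem sizes used in the validation suite

The suite recovers the calibrated hazard structure over 200 simulated
cohorts of 500 patients (checking mean coefficient bias below 10% and
Wald CI coverage between 90% and 98%), and checks the size of the NRI and
IDI z-tests over 1000 null cohorts of 323 patients at the study's event
rate, both chosen as the smallest designs at which the Monte-Carlo error is
comfortably below the asserted bands.  PRSA is verified against brute-force
enumeration on random series of up to 50 beats, and the spectral estimator
against closed-form Parseval values.

## Known limitations

* In-sample reclassification statistics are optimistic: refitting the full
  model on the same patients moves event predictions up and non-event
  predictions down, so the *expected* in-sample continuous NRI under a null
  added marker is positive (about +0.10 at n = 323, against a per-cohort SE
  of ~0.17).  The z-tests still hold their nominal size in the tested
  regime, but point estimates of NRI from nested in-sample fits should be
  read with this bias in mind; out-of-sample or cross-validated evaluation
  is the remedy when an unbiased magnitude matters.
* The NRI/IDI standard errors are the standard asymptotic forms; they do
  not account for the estimation of the underlying model coefficients.
* The generator's hazard model is exactly proportional; the Cox fit is
  correctly specified by construction, so recovery tests do not probe
  misspecification.
* GRACE scores are inputs throughout; the package never computes them.
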