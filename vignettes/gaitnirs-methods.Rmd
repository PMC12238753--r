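---
title: "Methods: split-belt adaptation metrics, fNIRS processing, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: split-belt adaptation metrics, fNIRS processing, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`gaitnirs` analyses split-belt treadmill adaptation experiments with
concurrent functional near-infrared spectroscopy (fNIRS). This vignette is
the package's account of its models and numerical choices: what is
computed, under which assumptions, which knobs matter, and what the test
suite does and does not establish.

## 1. Behavioural model

### Step length asymmetry

The behavioural unit is the stride. At each heel strike, step length is the
anterior-posterior distance (mm) between the two heel markers; because it
is a between-heel *difference*, rigid body translation on the treadmill
cancels (the body-centred reading, verified as an invariance test). Step
length asymmetry for stride $i$ is

$$\mathrm{SLA}(i) = \frac{\ell_\text{fast}(i) - \ell_\text{slow}(i)}
                         {\ell_\text{fast}(i) + \ell_\text{slow}(i)},$$

dimensionless, antisymmetric in its arguments and bounded in $(-1, 1)$ for
positive step lengths. Zero is symmetric gait.

### Learning curve

Split-belt walking (2:1 belt-speed ratio) perturbs SLA sharply negative;
it then relaxes toward an asymptote over hundreds of strides. Adaptation
and deadaptation curves are first baseline-adjusted by subtracting the
visit-specific mean SLA of the **last 30 baseline strides**, then fitted
with the single-exponential state model

$$y(n) = a\,e^{bn} + c, \qquad n = 1, 2, \dots$$

with amplitude $a$ (negative during adaptation), per-stride rate $b < 0$
and asymptote $c$, minimising the sum of squared errors. A two-rate model
is deliberately out of scope: the single exponential fits consistently
across impaired gait without per-participant tuning.

**Optimisation.** The SSE surface is fitted with a particle swarm
(constricted Clerc-Kennedy coefficients; defaults 50 particles, 500
iterations; box $a \in [-1,1]$, $b \in [-1, 0)$, $c \in [-1,1]$) followed
by a bounded quasi-Newton polish with the analytic SSE gradient. Two
safeguards are built in: one particle is always seeded at the best
constant fit $(0, \cdot, \bar y)$, so the reported SSE can never exceed
the constant-fit SSE; and fits at a box edge are flagged rather than
silently clamped. When $|a|$ collapses to zero the rate $b$ is
unidentifiable and the fit says so (`b_identifiable = FALSE`). Fits are
bit-reproducible under their seed. The test suite checks the swarm+polish
SSE against an independent separable-least-squares oracle (profile out
$(a, c)$ in closed form, search $b$ on a grid with golden-section
refinement) to within 1% on random noisy series.

### Windows and outcomes

All phase summaries are evaluated **from the fitted model** at integer
strides (a raw-data variant exists behind `source = "raw"` for sensitivity
analysis): Initial (strides 1-5), Early (6-30) and Late (last 30) windows
for each phase. From these:

* **early change** = Early-window mean (adaptation rate proxy), per phase;
* **adaptation magnitude** = Late Adapt − Early Adapt (positive as gait
  symmetrises); **deadaptation magnitude** is stored as Early Deadapt −
  Late Deadapt so a positive value means decay;
* **after-effect** = Early Deadapt mean relative to baseline (zero after
  adjustment, so it equals the Early Deadapt mean);
* **savings** = Visit 2 − Visit 1 difference at Initial and Early Adapt.
  The sign convention is deliberate: positive savings = less asymmetric
  (higher SLA) on re-exposure, i.e. faster relearning.

## 2. Synthetic cohort: the stated world

The generator exists so that every downstream stage is testable against
known truth. Its defaults are the experimental design being emulated: 28
people with multiple sclerosis (PwMS) and 20 healthy controls (HC), two
visits in a counterbalanced TENS ON/OFF crossover, phases Baseline (tied
belts) → Adaptation (split, 1000 strides) → Deadaptation (tied, 1000
strides), group mean step lengths 563 mm (PwMS) and 602.4 mm (HC).

Stride noise is independent Gaussian, sd 0.02 SLA units (an AR(1) option
exists, default off — the noise spectrum of real stride series is not
characterised in the source material). Between-participant variability:
stable amplitude and asymptote offsets (sd 0.03 and 0.01), a baseline
level offset (sd 0.01), and a Visit-2 *relearning offset* with sd
**0.037** — the between-participant savings sd of the stated world, chosen
so the injected TENS shift of +0.05 implies Cohen's $d \approx 1.35$.

**Effect injection.** Effects are stated in outcome units but injected on
the generating amplitude $a$, scaled by the exact window factor
$\bar E_w(b) = \operatorname{mean}_{n \in w} e^{bn}$ so that the realised
outcome shift equals the stated value. For example the TENS×visit savings
effect adds $0.05 / \bar E_{1:5}(b)$ to the Visit-2 adaptation amplitude
of PwMS who walk with TENS ON at Visit 2; recovering that +0.05 through
baseline adjustment, fitting, window means and the savings contrast is
then a genuine end-to-end pipeline test, not an identity. Group and visit
effects are injected the same way (group gap 0.022 on adaptation
magnitude; Visit-2 shifts on early change and after-effect).

What the generator does **not** emulate: washout-period forgetting between
visits, stride-to-stride autocorrelation (by default), kinematic detail of
individual steps, and any fNIRS-behaviour coupling. A green recovery test
therefore establishes that the pipeline inverts its own stated world — not
that the world is a complete model of impaired gait.

## 3. fNIRS pipeline

### Forward model (generator)

Long channels carry HRF-convolved block activation plus a shared scalp
component (slow perfusion drift, ~0.1 Hz Mayer wave, 1.1 Hz cardiac
pulsation), channel-specific linear drift, sparse motion spikes and white
noise; short (scalp) channels carry the scalp component without
activation, at half the measurement noise (close separations see scalp
physiology at high signal-to-noise — that is their purpose). Haemoglobin
dynamics are forward-projected through the Beer-Lambert relation to
optical density and raw intensity at 760/850 nm. Note the 1.1 Hz cardiac
fundamental is *below* the 3.05 Hz Nyquist frequency of 6.1 Hz sampling
and is represented without aliasing; only harmonics (not simulated) would
alias. The scalp-coupling-index band (0.5-2.0 Hz) therefore needs no
alias adjustment.

### Processing chain

intensity → optical density ($-\log_{10}(I/\bar I)$ per channel) →
haemoglobin via the modified Beer-Lambert law **without** a differential
pathlength factor (uniform 35-40 mm separations; only relative amplitudes
are analysed) → robust spike detection (moving-window z-score: 5-s lag =
round(5 × 6.1) = 31 samples, threshold 3.5, influence 0.5, 10 iterations)
→ temporal derivative distribution repair (TDDR: iterative Tukey-biweight
reweighting of the low-frequency derivative, reintegration, high band
restored; spike-masked samples bridged by monotone Hermite interpolation)
→ short-channel regression (the short channel with the highest absolute
correlation is projected out; residuals are exactly orthogonal to it) →
zero-phase Butterworth high-pass at 0.01 Hz (order 2) plus Gaussian
smoothing with −3 dB at 0.4 Hz (kernel sd
$\sqrt{\ln 2}/(2\pi \cdot 0.4) \approx 0.33$ s — the smoothing
convention had to be fixed here since upstream software does not document
its kernel) → z-normalisation per channel (the scale is retained so betas
can be mapped back to concentration units) → ordinary-least-squares GLM.

The GLM uses one regressor per 30-s block (boxcar convolved with the
canonical double-gamma HRF: response peak 6 s, undershoot peak 16 s,
dispersions 1 s, peak:undershoot 6:1), an intercept and a linear drift
term; the two block betas of a timepoint are averaged (a single
two-block regressor is available behind a flag). Block regressors are
normalised to **unit plateau**, so a beta is the sustained concentration
response of its block. When the data are temporally filtered, the same
filter is applied to the block regressors; this keeps the noiseless round
trip exact. ROI betas are arithmetic channel means over the six bilateral
clusters (PMd, PMv, M1, S1, SPL, IPL); contrasts are Early Adapt −
Baseline per channel/ROI. HbR is converted and written but not analysed.
The scalp coupling index (cardiac-band correlation of the two
wavelengths) is reported as QC only — **no automatic channel rejection is
performed**, deliberately.

### Numerical behaviour worth knowing

* **Robust stages are only identity-like against their assumed noise
  background.** On a mathematically noiseless record the derivative MAD is
  zero and every smooth response is an "outlier"; TDDR and the spike
  detector are therefore excluded from the exact noiseless round-trip
  test (the linear chain is exact to float tolerance) and tested on their
  own fixtures instead. On realistic noisy records the robust stages
  attenuate large smooth responses modestly (roughly 20-25% shrinkage of
  block betas in the standard fixture); group contrasts of z-normalised
  betas are unaffected in direction.
* **TDDR removes the net linear trend** (the robust mean of the
  derivative) by design; its near-identity test uses an integer number of
  sinusoid periods so trend removal is not confounded with distortion.
* The 0.01 Hz high-pass has a ~100 s time constant; series much shorter
  than three time constants trigger a warning, and edge padding
  (odd-reflection, steady-state initial conditions) controls the
  transients.

## 4. Statistical layer

Repeated outcomes are modelled as
`outcome ~ group * visit * tens + (1 | participant)` by REML (estimation
delegated to `lme4`). Sum-to-zero factor coding makes the marginal Wald
tests of each term's coefficients Type III tests. Satterthwaite
denominator degrees of freedom are computed in-package: the restricted
log-likelihood of the random-intercept model is written in closed form in
the two variance components, its Hessian (numerical) gives the asymptotic
covariance of the variance estimates, and each contrast's df follows from
the delta method ($\nu = 2v^2 / (\nabla v^\top A \nabla v)$), with the
eigenvector-wise combination for multi-df terms. In the balanced crossover
this reproduces the classical split-plot df exactly (48 participants in 4
group×order cells → df 44 for both strata), which the tests assert.
Singular random-effect fits fall back to fixed-effects `lm` with a
warning. Savings outcomes have one record per participant and are always
fitted without a random effect (residual df 44 in the full design).

Estimated marginal means average model predictions over the reference grid
with equal weights (equal to raw cell means under balance — tested);
pairwise contrasts carry Satterthwaite or residual df. The
Benjamini-Hochberg family is always an explicit argument — the package
never infers "within outcome and group" silently. Cohen's $d$ for a
contrast is computed from the observed records of the two cells with the
pooled-sd formula (the source convention is not documented; a model-based
variant is available via `d_method = "model"`, and a paired-difference
variant in `cohens_d(paired = TRUE)`). Backward stepwise regression drops
the least significant term by marginal F until all retained terms pass the
exit threshold (0.05, configurable), logging the elimination path.
Assumption checks are diagnostics, not gates.

## 5. Design decisions that were genuinely open

* **Heel-strike detection**: upward 20 N threshold crossing sustained for
  0.2 s (conventional for instrumented treadmills; the source does not
  state its detector). Marker positions at event times by linear
  interpolation (force sampled 10× faster than markers).
* **Marker smoothing**: a zero-lag 6 Hz Butterworth replaces
  generalised-cross-validated spline filtering, which is out of scope as a
  deliberate substitution.
* **Swarm hyperparameters**: the published PSO configuration lives in an
  external reference not reproduced here; defaults (50 × 500, bounds
  above, polish on) are stand-ins and fully configurable.
* **Savings and magnitude signs**: both orientations are derivable from
  the stored signed window means; the package's conventions (savings =
  V2 − V1, deadaptation magnitude = Early − Late) are documented above.
* **Exact spike/interpolation variants** of the upstream commercial
  software are proprietary; the robust-z detector and monotone Hermite
  bridging are documented interpretations.
* **GLM drift regressor**: included (whether the reference software does
  is undocumented; a divergence risk worth naming).

## 6. Runtime scaling in the test suite

The replicate-simulation acceptance tests (type-I control over 200
zero-effect cohorts; end-to-end savings recovery over 100 cohorts) run
the full pipeline with 250 strides per phase instead of 1000 and a
reduced swarm (12 × 40 + polish). This is compute scaling only: cohort
sizes, noise levels, the participant savings sd and the injected effects
are the stated world's. The polish step converges to the same local
optimum, so the scaling costs fit precision (slightly wider savings
noise), not validity.

## 7. Known limitations

Single-exponential only (no two-rate dynamics); no washout modelling
between visits; SNIRF files are neither read nor written (no HDF5 backend
in the supported environment — the tabular + JSON layout is the exchange
format); fNIRS group-level statistics reuse the behavioural mixed-model
machinery rather than channel-wise mixed models; DPF-corrected absolute
concentrations, image reconstruction and subcortical contributions are out
of scope.
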