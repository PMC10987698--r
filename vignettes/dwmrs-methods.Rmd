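---
title: "Diffusion-weighted MRS of brain metabolites: models, simulation and fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusion-weighted MRS of brain metabolites: models, simulation and fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwmrs)
```

## The measurement and the models

Diffusion-weighted MR spectroscopy (dMRS) measures how the signal of each
brain metabolite attenuates as diffusion weighting *b* increases. Because
most metabolites are confined to specific cell populations — N-acetyl-
aspartate and glutamate largely neuronal, myo-inositol and glutamine
largely astrocytic — their diffusion properties report on the
microstructure of those cells, complementary to water diffusion MRI.
`dwmrs` implements the full analysis chain for a paired, two-timepoint
rodent cohort in which a disease process (a hepatic-encephalopathy-like
contrast) raises glutamine severalfold, depletes the osmolytes, and
increases metabolite diffusivities.

Two signal models are fitted to each normalized decay:

**Randomly oriented sticks.** Metabolites diffuse effectively in one
dimension along thin processes (neurites, astrocytic branches) with
intra-stick diffusivity $D_{intra}$; orientation-averaging over an
isotropic stick distribution gives

$$\frac{S}{S_0} \;=\; \sqrt{\frac{\pi}{4\,b\,D_{intra}}}\;
\operatorname{erf}\!\left(\sqrt{b\,D_{intra}}\right)
\;=\;\int_0^1 e^{-b\,D_{intra}u^2}\,du .$$

`sticks_attenuation()` evaluates the closed form, switching to the series
$1 - x/3 + x^2/10$ for $b\,D_{intra} < 10^{-6}$ so the $b \to 0$ limit is
exact. The identity with the quadrature integral is enforced in the test
suite to $10^{-6}$.

**Cumulant (kurtosis) expansion.** The model-agnostic second-order
expansion of the log-signal,

$$\ln\frac{S}{S_0} \;=\; -b D + \tfrac{1}{6}(bD)^2 K ,$$

yields the apparent diffusion coefficient $D$ (ADC) and apparent kurtosis
$K$. For sticks-distributed diffusivities the low-$b$ limits are
$D = D_{intra}/3$ and $K = 3\,\mathrm{Var}(D_u)/E(D_u)^2 = 2.4$, which the
tests verify to 1%. The expansion has a finite radius of convergence: for
the sticks model it is set by the first zero $z_1$ of the error function
in the complex plane, $b_c = |z_1|^2 / D$. `radius_of_convergence()`
locates $z_1 = 1.45062 + 1.88094\,i$ by Newton iteration on
`pracma::erfz` ($|z_1|^2 \approx 5.6422$), so an assumed
$D = 0.3\ \mu m^2/ms$ gives $b_c \approx 18.8 \approx 19\ ms/\mu m^2$, and
the cumulant fit uses only $b \le b_c$ — on the default nine-point grid,
up to $b = 15.6$.

## Acquisition protocol and simulation

`acq_protocol()` defaults to a STEAM-like diffusion protocol: nine
b-values 0.4–25.1 ms/µm² with shot counts 160/160/160/160/160/320/480/
480/480 (more shots where attenuation is strongest), gradient duration
δ = 6 ms, diffusion time Δ = 120 ms, 5 kHz spectral width, 4096 complex
points, TE/TM = 15/112 ms at 9.4 T (400.2 MHz).

The simulator builds each single shot in the time domain as a
concentration-weighted sum of metabolite basis FIDs, attenuated per
metabolite by the sticks model at the shot's b-value, plus a broad
macromolecule component, then adds artifacts and complex Gaussian noise.
Key choices:

* **Basis set.** Each metabolite is 1–3 Lorentzian resonances at fixed
  catalogue chemical shifts with proton-weighted relative areas
  (`metabolite_catalogue()`), default linewidth 12 Hz. This deliberately
  collapses J-coupled multiplet structure: the package tests the fitting
  chain on basis-matched data, for which quantum-mechanical lineshape
  simulation adds nothing. Real spectra contain coupling evolution,
  baseline distortions and residual water that this generator does not
  emulate — passing tests demonstrate correctness of the chain, not
  LCModel-grade performance on in vivo data.
* **Macromolecules.** A fixed set of broad (90 Hz) resonances forming one
  basis component. Its diffusion attenuation is not part of the emulated
  conditions, so by default it does not attenuate with b; this is
  config-exposed (`mm_attenuates`, `mm_d`).
* **Noise.** Complex Gaussian in the time domain, per shot. The level is
  set by a target SNR of the *averaged* lowest-b spectrum, defined as the
  maximum real-part peak height in 1.8–4.2 ppm over the noise SD in the
  signal-free 8.5–10.5 ppm region. The default target is 40, in the upper
  part of the 15–45 range such acquisitions reach at the lowest b-value;
  at that level all seven default metabolites clear the 6% CRLB reporting
  rule, which is a precondition of the downstream diffusion analysis.
  SNR then falls naturally with b through the signal attenuation,
  partially compensated by the higher shot counts.
* **Artifacts.** Cumulative zero-order phase drift (0.004 rad/shot),
  frequency drift (0.02 Hz/shot) and Bernoulli amplitude dropouts
  (p = 0.02, depth 0.7) emulating motion-corrupted shots.
* **Paired cohort.** Animal-level log-normal effects: week-0
  concentrations and diffusivities vary between animals (CV 0.10 and
  0.08), and each animal draws its own week-6/week-0 ratio around the
  configured effect with a mean-zero log correction, so the expected
  ratio equals the configured one. The default effect table encodes the
  disease contrast: glutamine concentration ×2.78 (+178%), myo-inositol
  ×0.71 (−29%), glutamine $D_{intra}$ ×1.58 (+58%), with milder changes
  elsewhere. Ratio dispersions are calibrated so the SD of the
  per-animal percent change matches the cohort dispersions those effects
  are reported with (≈95 points for Gln concentration, 14 for Ins, 16
  for Gln diffusivity).

With week-0 glutamine $D_{intra} = 0.40\ \mu m^2/ms$, the +58% effect
propagates through the cumulant fit on the $b \le 15.6$ grid to a +35%
ADC change — the two effect sizes are mutually consistent under the
sticks model, which is a useful internal check of the configuration.

## Preprocessing

Shots are corrected per b-value block. The frequency offset of each shot
relative to the pointwise-median spectrum of its block is estimated by
windowed magnitude cross-correlation to the nearest bin, then polished —
together with the zero-order phase — by locating the spectral peak of the
time-domain cross-signal against the leave-one-out mean shot. Two
numerical points matter:

* The FID noise tail is excluded from the estimate (points where the
  mean-shot envelope falls below 5% of its maximum): late points carry no
  phase information but enormous leverage on a fitted frequency.
* Single-shot estimates at strong diffusion weighting sit at the
  information limit (σ ≈ 0.3–0.4 Hz at the default per-shot SNR). Since
  scanner drift is slow, the *applied* correction is the linear-in-shot
  trend of the raw estimates (phase trend fitted on unit phasors, robust
  to wrapping). Applying raw per-shot estimates instead would inject the
  estimation noise into the average and systematically destroy signal at
  high b — up to 20% amplitude loss in our experiments.

Outlier shots are rejected when their magnitude integral over
0.5–4.2 ppm drops by strictly more than `drop_threshold` (default 50%)
relative to the block median; a shot at exactly the threshold is kept.
The median reference caps the removable fraction at one half, and the
pipeline refuses blocks that would lose more. Retained shots are averaged
complex-valued, with the effective shot count recorded.

Eddy-current correction is represented by the zero-order phase
correction; no water-reference shot is simulated.

## Quantification and CRLB filtering

Averaged spectra are fitted in 0.2–4.3 ppm as a non-negative linear
combination of the basis (metabolites + macromolecule) plus an
unconstrained polynomial baseline (default order 2), by NNLS with
sign-split baseline columns. Because per-shot alignment is relative to
the block median, a common-mode frequency/phase offset can survive
averaging; the fit therefore first aligns the spectrum to the basis,
iterating template refinement (fit, rebuild template from fitted
composition, re-align) so the alignment is unbiased on basis-matched
data — the chain recovers noiseless amplitudes to machine precision.

Relative CRLBs come from the linear model conditional on the fixed
lineshape: $\sigma^2 (A^T A)^{-1}$, square-rooted, divided by the
amplitude (infinite, flagged, at zero amplitude). This understates the
uncertainty of a full nonlinear lineshape fit, which is acceptable here
because the simulation is basis-matched. Metabolite reporting follows
the two CRLB rules used in vivo: concentrations are reported for
metabolites below 25% relative CRLB at week 0 in every animal (a loose
criterion that protects low-concentration metabolites), diffusion
analyses only for metabolites below 6% at the lowest b-value in every
animal (strict, to limit error propagation into the decays). Selection
is by metabolite name — never of individual values — and the thresholds
are strict inequalities.

## Decay fitting

Per animal, timepoint and metabolite, amplitudes are normalized to the
lowest b-value (0.4 ms/µm²). The sticks model is fitted to the
normalized decay over the full b-range by bounded Levenberg–Marquardt
(`minpack.lm`), $D_{intra} \in [10^{-4}, 3]$, initialized at three times
the two-point ADC; the normalization fixes the amplitude factor at 1.
The cumulant model is fitted on $\ln s$ restricted to $b \le b_c$
(b_c rounded to 3 significant figures before the comparison). Written
for a curve normalized at $b_0$,

$$\ln s(b) = -(b - b_0)\,D + \tfrac{1}{6}\left(b^2 - b_0^2\right) D^2 K,$$

which is linear in $(D,\ D^2K)$; the least-squares problem is therefore
solved exactly in closed form rather than by an iterative solver, with
standard errors from the linear covariance and a delta-method propagation
for $K$. Estimates outside $D \in (10^{-4}, 3]$, $K \in [-1, 10]$ are
flagged as non-converged. Fitting the log-signal changes the noise model
relative to fitting $s$ itself (log-normal rather than additive errors);
this is the form the expansion is written in and the form used here.

Both aggregation routes are computed and labeled: per-animal fits
summarized as mean ± SD, and a fit of the group-average curve (the
pointwise mean of the normalized per-animal curves — normalized-mean
rather than mean-of-raw, so animals with different absolute signal
contribute equally).

Because each animal's percent change divides by its own noisy week-0
estimate, the mean percent change of a fitted parameter carries a
positive skew relative to the generating effect. For week-0 glutamine —
low concentration, hence ≈11% per-animal uncertainty on its fitted
diffusivity at the default SNR — this amounts to roughly +8 percentage
points on the recovered D_intra and ADC changes (measured against the
generator truth over ten cohorts), and it widens the recovered
per-animal dispersion beyond the configured one. The per-fit estimates
themselves are unbiased; the skew belongs to the mean-of-ratios
estimator, which is the field's standard reporting convention and is
therefore kept. Comparisons of recovered effect sizes against externally
reported ones should expect this overshoot whenever the reported values
are configured directly as the generating truth.

## Cohort statistics

The long cohort table (animal × timepoint × metabolite, one row per
parameter) feeds a classical univariate repeated-measures two-way ANOVA
with disease (week) and metabolite as within-subject factors and the
animal as blocking factor: each main effect is tested against its
interaction with the subject, the interaction and the subject-matching
line against the three-way residual. No sphericity correction is
applied. Post-hoc per-metabolite week-6 vs week-0 comparisons use, by
default, the pooled within-subject error (week×subject and residual
strata combined); a paired-t variant is config-switchable since the
exact post-hoc error term behind commercial implementations is not
standardized. Bonferroni adjustment multiplies raw p by the number of
retained metabolites (config-overridable), capped at 1. The F statistics
are validated against an explicit sums-of-squares oracle to $10^{-10}$,
and the disease-effect type-I error calibrates to ≈5% over 1000 null
cohorts.

Percent changes are mean ± SD across animals of
$100\,(x_{w6}-x_{w0})/x_{w0}$; for sign-indefinite parameters
(kurtosis can cross zero) the percent change is reported as `NA` rather
than a misleading ratio.

## Pipeline, determinism and problem sizes

`run_pipeline()` composes the stages, generating and reducing shot data
one animal × timepoint at a time so that peak memory stays near a single
b-block (~30 MB) even at the full protocol. Every stage's output is
written to the run directory as diffable CSV/JSON with a schema version,
and a single seed drives all randomness: two runs with the same
configuration are byte-identical. `simulate_cohort()` materializes the
full shot-level dataset instead, for workflows that need the raw shots.

Problem sizes used by the packaged checks: unit tests exercise the
spectral chain on a reduced grid (1024 points, 8–24 shots per b — same
12.5 ppm span, coarser sampling) chosen so the whole suite runs in
minutes; the effect-recovery checks and the acceptance script run the
full protocol (4096 points, 160–480 shots per b, five animals, two
timepoints) over ten seeds and pool the per-animal percent changes.
Monte-Carlo calibrations use 200 draws (fit coverage, estimator SE) and
1000 cohorts (ANOVA type-I).

## Known limitations

* Lorentzian singlet basis: no J-evolution, so fitting degeneracies of
  real Glu/Gln multiplets are under-represented; CRLBs are accordingly
  optimistic.
* The macromolecule diffusion behaviour is assumed (non-attenuating by
  default) rather than measured.
* Zero-order (frequency-independent) phase correction only; no
  time-dependent eddy-current model, no water referencing, no T2 or
  water-concentration scaling — concentrations are in arbitrary units
  and only within-cohort contrasts are meaningful.
* The trend-smoothed drift correction assumes slow drift; isolated
  single-shot frequency glitches are estimated (and reported) but not
  individually corrected — severe ones surface as dropout rejections.
* Per-animal ratio skew discussed above: mean percent changes of fitted
  parameters slightly overstate the generating effect when week-0
  estimates are noisy.
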