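---
title: "Quantifying golden-ratio organization of theta-alpha EEG spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying golden-ratio organization of theta-alpha EEG spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phispec)
```

## The model

Resting-state EEG carries two prominent slow rhythms: theta (4–8 Hz) and
alpha (8–13 Hz). A long-standing proposal holds that the canonical
frequency bands are not arbitrary but spaced roughly by the golden ratio
(φ ≈ 1.618), because oscillators whose frequencies stand in the "most
irrational" ratio never align their excitatory phases — the configuration
that minimizes spurious cross-frequency synchronization. The alternative
organization is harmonic: a 2:1 frequency ratio that maximizes recurrent
phase alignment and is associated with active coupling.

`phispec` measures where an individual sits between these two regimes.
Each subject is summarized by the ratio of band *spectral centroids*

  R = f_α / f_θ,   f_band = Σ f·P(f) / Σ P(f) over the band,

and by the **Phi Coupling Index**

  PCI = ln( (|R − 2| + ε) / (|R − φ| + ε) ),  φ = 1.618034, ε = 0.01.

PCI is positive when R is strictly closer to φ than to 2, negative in the
harmonic regime, zero exactly at the midpoint (φ+2)/2 = 1.809017, and
finite for every positive R. The centroid (rather than a spectral peak
such as the individual alpha frequency) is used because it remains defined
when peaks are weak — common in the theta band — at the cost of
sensitivity to broadband spectral shape, which the aperiodic correction
below addresses.

The companion quantity is **theta–alpha convergence**, a bounded transform
of the centroid separation:

  C = 1 / (|f_α − f_θ| + 0.5),

which ranges from about 0.1 at the physiological maximum separation
(≈ 9 Hz) to 2.0 when the centroids meet near the 8 Hz band boundary. The
package's central estimator, `pci_fit()`, returns the cohort-level
association between PCI and C with bootstrap confidence intervals, and the
validation battery asks whether that association could be an artifact of
the two indices sharing the same inputs.

## Processing chain and its tunables

`analyze_recording()` implements the recording-to-row pipeline:

* **Bandpass 1–45 Hz**, windowed-sinc FIR (Hamming), applied
  forward-backward so the phase is zero. Transition bandwidth follows the
  usual quarter-of-the-edge heuristic (clamped to the room available), and
  the filter length is 3.3 divided by the narrowest transition. These
  mirror the defaults of the mainstream EEG tooling this pipeline is
  modeled on.
* **Bad channels**: a channel is flagged when its variance exceeds the
  mean channel variance by 3 SD of the channel variances. Note an
  algebraic consequence: because the outlier inflates the SD it is judged
  against, a single bad channel can only be caught when enough channels
  are present (the attainable z among n channels is (n−1)/√n, so n ≥ 11
  for z = 3). With identical channels the spread is zero and nothing is
  flagged. Flagged channels are rebuilt by inverse-squared-distance
  weighting of the good channels on an idealized 10-20 sphere — a
  deliberate simplification of spherical-spline interpolation, adequate
  here because interpolation only feeds band-averaged PSDs (a test checks
  that interpolating versus dropping a channel moves band centroids by
  less than 0.05 Hz on synthetic data).
* **Average reference**, then **4 s consecutive non-overlapping epochs**;
  an epoch is rejected when any sample on any channel exceeds 100 μV in
  absolute value. "±100 μV" is read as an absolute single-sample bound,
  not peak-to-peak.
* **Welch PSD**: 4 s Hann windows, 50% overlap, computed inside epochs and
  averaged across them (equivalent to Welch on concatenated clean data
  with windows that do not cross epoch joins). Native resolution 0.25 Hz.
* **Common grid**: spectra are averaged into 1 Hz bins [k−0.5, k+0.5),
  the grid on which multi-dataset cohorts are pooled; `grid = "native"`
  keeps the 0.25 Hz resolution. Both paths are tested.
* **Bands and groups**: theta [4, 8), alpha [8, 13) — half-open so the
  8 Hz bin belongs to alpha and nothing is double-counted. Alpha is read
  from the posterior group (O1 O2 Oz P3 P4 Pz P7 P8), theta from the
  posterior group by default or from the frontal group (Fz F3 F4) in the
  frontal-theta variant.

The log base of PCI only rescales the index (any base change is a positive
multiplicative factor), so signs, ranks and correlations are
base-invariant; the natural log is used and reported.

## Aperiodic correction

To separate oscillatory from broadband 1/f structure, `fit_aperiodic()`
fits log10 P = offset − χ·log10 f over 1–40 Hz with a robust two-pass
procedure: an OLS fit, then a refit on the bins lying at or below the
initial line (positive residuals are clamped and bins above their 2.5th
percentile excluded), so narrow-band peaks do not tilt the estimate. This
is a deliberate reduction of full spectral parameterization — no Gaussian
peak model is fitted because only the aperiodic line is consumed
downstream. `subtract_aperiodic()` removes the line in log-power space and
clamps negative residuals at zero; corrected centroids weight frequencies
by this nonnegative log-power residual (any positive weighting yields a
valid centroid; the residual is *not* back-transformed to linear power,
a choice the output documents). Subjects whose whole band is clamped to
zero are excluded from the corrected analysis and logged.

## Validation battery

Because PCI and convergence are both functions of (f_θ, f_α), part of any
correlation between them is mathematically built in. `full_report()`
therefore runs:

1. **Null A, marginal resampling** (`null_marginal_resample`): theta and
   alpha centroids resampled independently from their empirical marginals
   (draw size = cohort size by default; permutation mode available),
   destroying the joint dependence. Summarized by the null mean/SD, the
   z-score (r_obs − mean r_null)/SD(r_null), and the exceedance count.
2. **Null B, band-constrained Monte Carlo** (`null_band_constrained`):
   independent truncated-normal pairs inside [4, 8) and [8, 13) matched to
   the cohort's means/SDs. Sampling uses the inverse-CDF construction,
   which is exact and has no pathological rejection rates for narrow
   bands.
3. **Robust statistics**: Spearman alongside Pearson (`correlate()`), with
   p-values from `stats::cor.test` (exact below n = 10 without ties) and
   percentile bootstrap CIs (10,000 resamples by default).
4. **φ-specificity sweep** (`phi_sweep`): the generalized index is
   recomputed for reference constants 1.30–2.20 in steps of 0.05, with φ
   itself inserted into the grid so it is evaluated exactly. Two forms are
   exposed, because the harmonic anchor's role in the sweep is a genuine
   design fork: the primary *proximity* form −ln(|R − c| + ε) is defined
   for every c including 2.0; the *two-anchor* form
   ln((|R − 2| + ε)/(|R − c| + ε)) keeps 2:1 as the fixed alternative and
   is undefined by convention at c = 2 (recorded as missing). Neither is
   claimed to be canonical; both are tested.
5. **ε-sensitivity** (`epsilon_sweep`): PCI recomputed across
   ε ∈ {0.001, 0.01, 0.1, 0.5, 1.0}. The Pearson correlation's sign is
   stable whenever the baseline association is away from zero, but the
   index is *not* a monotone transform of itself across ε for subjects on
   opposite sides of φ, so Spearman correlations may change — the test
   suite carries a four-subject counterexample where the rank correlation
   moves from +0.2 to −1.0 between ε = 0.001 and ε = 1.
6. **Frontal-theta variant** (`frontal_theta_variant`): the index
   recomputed with frontal theta against posterior alpha, aligned by
   subject; if posterior theta were mere volume-conducted alpha, the
   frontal variant should weaken, so its direction is diagnostic.

Plus partial correlation controlling for age, median-split frequency
profiles (ties to the low group, deterministically), and subgroup
correlations by sex and by an age < 40 split. No multiple-testing
correction is applied anywhere (two-tailed α = 0.05 throughout), matching
the analysis style this battery reproduces.

### The sign of the band-constrained null

A point worth documenting because it is easy to get wrong: the mean of the
Null B correlation distribution is *not* structurally negative. Simulation
with this package shows its sign tracks where the implied mean ratio sits
relative to the midpoint 1.809: cohorts whose band means imply ratios
mostly *below* ≈ 1.6 (slow alpha, fast theta — e.g. θ ≈ 6.5 ± 0.5 Hz,
α ≈ 9.6 ± 0.8 Hz, where the null mean is ≈ −0.28) give negative null
means, while means implying ratios above the midpoint give positive ones.
The package's negative-direction regression test therefore pins the
slow-alpha/fast-theta parameter regime explicitly rather than treating
the sign as universal.

## The synthetic-data generator

`synth_spec()`/`make_cohort()` emulate eyes-closed resting EEG well enough
to exercise every module offline: an 11-channel 10-20 subset (covering
both analysis groups), a theta and an alpha sinusoid with random phases,
and independent per-channel 1/f^χ noise (spectrally shaped white noise,
χ = 1 by default). Per-subject true ratios are drawn from
Normal(1.677, 0.142) — the cohort statistics the method targets — with
theta uniform on [4.5, 7.5] Hz and the ratio truncated per subject so the
implied alpha stays inside [8.25, 12.75] Hz. Two consequences of that
truncation are worth knowing: the realized mean ratio sits ≈ 0.02 below
the nominal 1.677 (low theta draws force the ratio up, high ones force it
down, asymmetrically), and a few percent of subjects fall close enough to
a band edge that a 1 Hz-grid centroid cannot recover their frequency to
0.5 Hz — tones above ≈ 7.35 Hz put most of their Welch mainlobe into the
[7.5, 8.5) bin, which belongs to alpha, and tones above ≈ 12.4 Hz put
mass outside [8, 13) altogether. The parameter-recovery suite runs 50
subjects at these exact conditions and tolerates 5% such failures.

Calibration choices the generator fixes (and what they mean): oscillation
amplitude 15 μV so that clean signals stay clear of the 100 μV rejection
bound; `snr` defined as one oscillator's power over the *total* broadband
noise power per channel (default 2); amplitude gains of 2 for theta on
frontal channels and alpha on posterior channels over a unit base gain, so
both rhythms are measurable everywhere but regionally maximal, which is
what makes the frontal-theta variant meaningful on synthetic data. An
optional slow amplitude modulation of alpha (waxing–waning) is off by
default so the spectral examples stay analytic. Ages are uniform on 20–77
and sex is balanced, purely to exercise the demographic code paths — no
demographic effect is planted.

What the generator does *not* emulate: volume conduction and source
geometry (regional structure is injected directly through gains), peak
width and asymmetry of real alpha, non-stationarity beyond the optional
envelope, and real artifact morphology. Passing tests therefore show the
*estimator chain* is correct under the stated spectral model; they do not
certify performance on real recordings.

For the specificity sweep, `synth_coupled_cohort()` builds cohorts whose
ratios cluster at a chosen constant c* and whose centroid separation
grows with |R − c*|. The separation is drawn inside the feasibility window
common to the whole cohort (the bands force the feasible separation to
grow with R; using a common window removes that monotone drift, which
would otherwise drag the sweep's argmax toward the low end of the grid
regardless of c*). With this construction the sweep recovers
c* ∈ {1.5, φ, 1.9} to within one grid step for both sweep forms.

## Numerical choices and degenerate inputs

* PCI at the midpoint is zero only up to double rounding of the printed
  φ; tests assert |PCI| < 1e-12 rather than exact zero.
* `pci` errors on R ≤ 0; `convergence_unbounded` errors at zero
  separation (the documented reason the bounded form is primary).
* Centroids error (and the subject is excluded, with a logged reason)
  when a band holds no positive power; this includes fully clamped
  aperiodic residuals.
* Bad-channel detection returns an empty set when the variance spread is
  zero; median-split ties go to the low group; a stratum below n = 3 is
  skipped with a warning; a constant covariate degrades partial
  correlation to plain Pearson with a warning, and a variable numerically
  fully explained by the covariate yields a partial correlation of 0
  rather than rounding noise.
* Every stochastic routine takes a `seed` and runs on a private RNG
  stream, restoring the caller's `.Random.seed`; identical seeds give
  bit-identical results.
* Degenerate null-model draws (zero variance) are skipped and counted,
  never silently dropped.

## Problem sizes used by the shipped checks

The package's own test battery and acceptance script run entirely on
synthetic data at deliberately modest sizes: 50 pipeline subjects for
parameter recovery, 300-subject ratio cohorts for the φ-organized
fraction, 2,000 draws for the band-constrained null, a few hundred draws
for marginal-resampling regression checks, and 300-subject coupled
cohorts per sweep constant. These sizes were chosen so the whole battery
completes in a couple of minutes while keeping Monte-Carlo error well
inside the asserted tolerances; all of them are parameters, and users
reproducing a full-scale analysis should raise them to the defaults
(100,000 and 10,000 draws, 10,000 bootstrap iterations).

## Known limitations

* The published effect sizes for this method were estimated on two public
  EEG repositories; reproducing them requires downloading those
  recordings and is deliberately out of the offline test scope. The
  package ships the harness (`analyze_directory()` over EDF/BrainVision
  files) for users who have them.
* The EDF and BrainVision readers cover the common continuous layouts
  (16-bit EDF, multiplexed INT_16/IEEE_FLOAT_32 BrainVision) and refuse
  mixed sampling rates rather than resampling.
* Spherical-spline interpolation is approximated by inverse-distance
  weighting; channels absent from the built-in 10-20 table fall back to
  the good-channel mean with a warning.
* Centroids on the 1 Hz grid are intrinsically quantized; frequencies
  within ~0.5 Hz of a band edge cannot be recovered to better than the
  bin structure allows (see the generator section).
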