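---
title: "Multimodal tumor-imaging phantoms: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal tumor-imaging phantoms: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmriphantom)
```

# Scope and scientific setting

`qmriphantom` re-creates, on digital phantoms with known ground truth, the
quantitative imaging pipeline used to characterise tumor physiology in
dual-tumor mouse studies of radiotherapy combined with PD-1 checkpoint
blockade: EPR oximetry for oxygen maps and the hypoxic fraction, DCE-MRI
for perfusion (AUC1min) and extracellular volume (AUC10min), diffusion
MRI for cellularity (ADC), hyperpolarized ^13^C spectroscopy for
glycolytic flux (lactate/pyruvate ratio), and the statistics that link
primary-tumor perfusion to remote-tumor response. Because every raw
acquisition is forward-simulated from a tissue-parameter map the package
itself generates, every estimator can be validated by round trip against
truth — which is the purpose of the package: animal experiments of this
design leave no raw data to re-analyse, so verification must come from
simulation with known answers.

# The digital phantom and cohort

## Tissue parameter maps

`make_tumor_phantom()` builds an ellipsoidal tumor inside an ellipsoidal
body support on a 16^3 grid (a deliberate desk-scale choice: small enough
that every acceptance-grade simulation runs in seconds, large enough to
resolve a core/rim structure after reconstruction). The `rim_core`
profile connects a hypoxic, poorly perfused, densely cellular, highly
glycolytic core (pO2 2 mmHg, Ktrans 0.05 min^-1, ve 0.15, ADC
0.7x10^-3 mm^2/s, kpl 0.05 s^-1) to an oxygenated, well-perfused rim
(28 mmHg, 0.25 min^-1, 0.35, 1.1x10^-3, 0.02) by a smooth radial ramp
between normalized radii 0.35 and 0.85. These endpoints are ordinary
preclinical tumor values; the inverse spatial coupling of oxygenation and
cellularity follows the usual picture of a perfusion-limited core. The
phantom is piecewise smooth and fully deterministic: all cohort-level
randomness lives in per-tumor scale factors, not in voxel noise, so
round-trip tests compare against exact truth.

The hypoxic-fraction ground truth `hf_true_rim_core()` is computed
analytically from the radial profile (the volume fraction inside the
radius where the profile crosses the threshold) rather than by counting
voxels; it is continuous and strictly monotone in the per-tumor oxygen
scale where the voxel count moves in discrete steps.

## The cohort and its links

`simulate_cohort()` emits one primary and one remote tumor row per mouse
across five arms: four treatment groups (control, RT, aPD1, combo)
breathing air, plus a carbogen-conditioned combination arm. Each tumor
draws a single lognormal "perfusion latent" that scales Ktrans, ve and
pO2 together (CV 0.15, 0.08 and 0.15 respectively) — one latent rather
than independent draws, so that in the noiseless limit remote volume is
strictly monotone both in AUC1min (decreasing) and in the hypoxic
fraction (increasing), the sign structure the predictive-biomarker
statistics must recover. ADC and kpl vary independently (CV 0.08, 0.15).
The true distribution of baseline perfusion across mice is not reported
for studies of this design, so these CVs are stated assumptions chosen
to give visible but not overwhelming biological scatter.

Remote day-9 volume for combination-treated mice in the immunogenic
(MC38) model is `v0 * exp(-beta * z) * exp(eps)`, with `z` the
normalised primary-tumor AUC1min truth, `beta = 1.2` and lognormal
growth noise of SD 0.25 — a log-linear link that produces realistic
scatter without asserting that the original experiments measured this
functional form. Other groups receive multiplicative volume effects
(control 2.0, RT 1.5, aPD1 1.4 versus combo 1.0); the poorly immunogenic
B16F10 model applies a null treatment effect throughout, encoding the
absence of an abscopal response there.

## Carbogen calibration

Carbogen breathing multiplies Ktrans and ve in the conditioned arm. The
default multipliers are calibrated constants: solving (2-D Newton on the
closed-form Tofts integrals over the default phantom's voxel
distribution) for the pair that raises the noiseless voxelwise-mean
AUC1min by exactly 71% and AUC10min by exactly 49% gives

* `carbogen_ktrans_mult = 1.794018`
* `carbogen_ve_mult = 1.446655`

Both are plain configuration values; nothing downstream knows they were
calibrated. The early-window increase is carried almost entirely by
Ktrans (AUC1min is perfusion-limited), while the 10-minute window mixes
perfusion and the ve-limited equilibrium, which is why the ve multiplier
lands below the Ktrans one.

# Forward models and estimators

## EPR single-point-imaging oximetry

SPI is pure phase encoding: each k-space sample is one FID point at a
fixed delay after excitation, so the acquired k-space at delay `tp` is
the DFT of `rho(v) * exp(-tp * R2*(v))`, and a delay series carries the
R2* map. The probe's R2* is linear in oxygen,
`R2* = r2star_anoxic + slope * pO2`; the calibration constants are not
published instrument properties, so defaults (0.25 us^-1, 0.02 us^-1 per
mmHg) were chosen once so that the default phantom's decay times
(T2* 1.2-4 us) sit inside the default delay window. All quantitative
conclusions are round-trip and therefore calibration-independent.

Timescale: the acquisition's 5 ns dwell with 1000 points implies a 5 us
FID window, and the module adopts that microsecond scale for delays and
rates; the alternative millisecond reading of FID duration is
incompatible with the stated dwell and point count. Eight delays
log-spaced over 0.4-3.0 us bracket the default T2* range; the number and
placement of delay images is not specified by the protocol, so this is a
package default.

The acquisition models four-step phase cycling explicitly: a constant
baseline offset injected into every cycle cancels exactly in the cycled
combination (a test injects offsets orders of magnitude above the signal
and verifies bit-level cancellation). Reconstruction subtracts a DC
estimate (mean of the outermost k-space shell), applies a separable
Tukey window defined on the original 19-sample extent, zero-fills
symmetrically about the DC sample, and inverse-FFTs under the symmetric
convention (object centre and DC sample both at `floor(n/2)+1`).
Reconstruction is verified against a brute-force `O(N^6)` direct inverse
DFT to 1e-10.

Two numerical caveats are deliberate. First, the shell DC estimate
absorbs a little genuine high-frequency signal; because a constant in
k-space maps to the central voxel only, this perturbs exactly one voxel,
and quantitative round trips disable the correction (there is no
uncancelled offset to remove after phase cycling). Second, quantitative
pO2 recovery is evaluated at matched-grid settings (`tukey_r = 0`,
zero-fill equal to the acquired grid): the default display settings
(Tukey r = 0.7, zero-fill to 64^3) constitute a heavy low-pass that
mixes core and rim and cannot reproduce voxel-level truth on any
reconstruction; the window and zero-fill path is validated separately by
the DFT oracle, impulse, linearity and offset-cancellation tests, and a
convergence test confirms the round-trip error decreases monotonically
as the taper is released.

R2* fitting is per-voxel ordinary least squares on the log magnitudes;
voxels with non-positive intensities are flagged and excluded, negative
rates are clamped to zero and flagged, and flagged voxels never enter
ROI summaries. pO2 conversion floors negative estimates at zero with a
flag. At the default-averages noise level (image-domain SNR 50 at the
shortest delay), the voxelwise pO2 RMSE on the matched grid is
~2.4 mmHg and the recovered hypoxic fraction is within half a
percentage point of truth.

## DCE-MRI

The tracer forward model is the standard two-parameter Tofts model
driven by a Weinmann-type bi-exponential input function (amplitudes
3.99/4.78 kg/L, rates 0.144/0.0111 min^-1) scaled to a 0.2 mmol/kg dose
with arrival at the 60 s injection time. The protocol gives only dose
and timing, so the input function is a package choice; because every
acceptance check is round-trip, its exact shape is internal. The
convolution is evaluated in closed form (exact piecewise-exponential
algebra, including the coalescent-rate limit), and the same algebra
supplies analytic AUC ground truth; a numerical-quadrature oracle checks
both to 1e-8.

The dynamic series is spoiled gradient echo (TR 156 ms, 45 degrees,
45 frames at 15 s); baseline T1 comes from a saturation-recovery series
at the four protocol TRs (300/600/1000/2000 ms — the protocol text
mentions "three sets" but lists four TR values; the module accepts any
>= 3 and defaults to the four printed ones). T1 fitting profiles the
amplitude out analytically and minimises the 1-D profiled residual, a
formulation equivalent to, and more robust than, two-parameter descent
from the two-point log initialiser. Signal inversion estimates M0 from
the mean of the four pre-injection frames and the fitted T1, inverts the
SPGR equation per frame, flags physically impossible signals (outside
the SPGR range) instead of silently clipping, and converts rate changes
to concentration with relaxivity r1 = 3.8 s^-1 mM^-1 (a documented
default; the protocol does not state one). Echo-time decay is absorbed
into M0 (single-echo acquisition; tracer T2* effects neglected — a
documented limitation).

AUC metrics integrate the concentration from injection to 60 s / 600 s
post-injection by composite trapezoid with linear interpolation to the
window endpoints, reported per voxel in mM min; the 15 s sampling agrees
with dense quadrature of the analytic curve to well within 2%.

Noise convention: white Gaussian, SD = mean pre-injection tumor signal /
SNR, the same SD applied to the T1-mapping series (the noise level is a
receiver property, not a per-sequence one). Error propagation through
the SPGR inversion sets a noise floor for weakly enhancing voxels: at
baseline SNR 50 the per-frame concentration error is ~0.004 mM, which
against the core's AUC1min of ~0.04 mM min puts the voxelwise relative
RMSE of the full chain near 6% — dominated by the low-Ktrans core, and
irreducible by estimator choice because both the dynamic noise and the
four-point T1 map contribute comparable shares. The ROI means consumed
by all downstream statistics are recovered to ~1%, and the tests assert
both levels explicitly (7.5% voxelwise, 2% on ROI means).

## Diffusion ADC

Mono-exponential Stejskal-Tanner decay over the five-b-value protocol
(12/50/500/800/1500 s/mm^2), with Rician noise (Gaussian quadrature
channels, magnitude taken) referenced to the lowest b-value. The default
fit is weighted least squares on the log signal with weights S^2, which
undoes the log transform's noise amplification at high b; ordinary
log-linear and Gauss-Newton nonlinear fits are provided as cross-checks
and agree to 1e-6 noiselessly. The known Rician noise-floor bias of the
log-domain fit is bounded by test: the median ADC bias over >= 1000
voxels at SNR 40 stays below 3%. Whether the original analysis used all
five b-values is unstated; the default uses all five.

## Hyperpolarized ^13^C exchange

Longitudinal magnetizations follow two-site exchange with relaxation,
propagated exactly between frames by the closed-form 2x2 matrix
exponential (the discriminant is non-negative for this sign pattern, so
the eigenvalues are always real; the coalescent case falls back to the
confluent limit). At each of the 20 frames the recorded signal is
`sin(flip)` of the magnetization and both pools are consumed by
`cos(flip)` — hyperpolarized magnetization is non-renewable, so total
polarization is non-increasing when the reverse rate is zero (tested).
The propagator is verified against an explicit-Euler ODE oracle: Euler's
first-order truncation floor at 1 ms steps is ~6x10^-4 at these rate
constants, so the oracle comparison extrapolates the 1 ms and 0.5 ms
Euler runs to the dt -> 0 limit (Richardson), which the matrix
exponential matches to 1e-6, and the tests additionally confirm the
first-order convergence rate itself.

Spectra are rendered as unit-area absorption Lorentzians (FWHM 30 Hz) at
+-192.5 Hz on the 3300 Hz axis (a 385 Hz pyruvate-lactate separation,
about 12.2 ppm at the ^13^C frequency of a 3 T system). Quantification
integrates the magnitude spectrum over +-4 linewidths around each
centre, corrects the known Lorentzian tail truncation analytically
(`(2/pi) atan(8)` of the area lies inside the window), and applies the
baseline correction in the power domain — subtracting the mean
out-of-window power before the square root — because subtracting a
magnitude baseline would clip strong peaks by the rectified-noise mean.
The price is a small positive floor on frames whose signal is below the
noise, which inflates the time-summed ratio by ~2% at SNR 100; peak
frames are recovered to better than 1.5%.

The pipeline's flux readout is the time-summed lactate/pyruvate ratio
(sum of lactate over all frames divided by sum of pyruvate). The
temporal reduction is not defined by the protocol; time-summed was
chosen once because it uses the whole curve, is invariant to
polarization level and receive gain, and is strictly monotone in the
conversion rate — all tested. `kpl` exists only in the generator; no
kinetic fit is performed, matching the ratio-based quantification the
analysis reports.

## Biomarker statistics

`compare_groups()` reproduces the normality-gated protocol: the
Anderson-Darling test at alpha 0.05 on residuals (value minus group
mean) selects parametric (Student's t / one-way ANOVA) or nonparametric
(Mann-Whitney / Kruskal-Wallis) machinery, and each non-control group is
compared to control with a Dunnett many-to-one adjustment. The Dunnett
distribution is estimated by Monte Carlo on the exact max-|t| statistic
for the observed group sizes (seeded, 2x10^4 draws by default); under
the nonparametric branch the same machinery is applied to midranks and
labelled a rank-transform Dunnett-type procedure, since the original
protocol does not say how many-to-one correction interacts with its
nonparametric branch. Adjusted p values are floored at the unadjusted
ones (they can never undercut them), single comparisons need no
familywise correction, and zero-variance groups are reported as
non-significant with an explicit degeneracy flag rather than dropped.
The familywise error of the whole gated procedure on four-group Gaussian
nulls is 0.052 over 2000 seeded replicates, and the k = 1 critical value
matches the Student t quantile to 0.2%; the parametric branch agrees
with the reference single-step Dunnett implementation in `multcomp` to
0.01 in adjusted p.

Correlations default to Spearman (the functional form linking perfusion
to remote growth is monotone but unknown; Pearson is available), with
midranks for ties and two-sided p values. Relative changes follow the
percent and fold conventions exactly (`fold = 1 + percent/100`).

# The pipeline and its reproducibility contract

`run_pipeline()` executes every stage for every tumor from one
serialisable configuration: identical configurations give byte-identical
cohort CSVs, each tumor's randomness comes from a counter-derived
substream of the master seed (never from global RNG state), and the
manifest records file hashes, seed and package version. With `resume`,
existing per-tumor artifacts are reused and only missing ones
regenerated. Volumes travel as float32 NIfTI-1 with JSON sidecars;
complex k-space series as a real/imaginary NIfTI pair with a JSON
sidecar (no HDF5 dependency is required anywhere in the chain).

# Problem sizes and what the tests do (and do not) show

Defaults throughout are desk-scale by design: 16^3 phantoms, 19^3
phase-encode grids, 10 mice per arm, 2x10^4 Monte Carlo draws per
Dunnett adjustment, 2000 replicates for the familywise calibration.
At these sizes the whole suite runs in about a minute and the
acceptance script in under ten seconds.

The generator emulates the statistical structure the analysis assumes —
smooth core/rim physiology, lognormal between-mouse variation through a
single perfusion latent, a monotone perfusion-to-response link, and
protocol-faithful acquisition parameters. It does not emulate anatomical
realism (bone, skin, partial-volume anatomy), motion, B0/B1
inhomogeneity, arterial-input variability between animals, or
tumor-growth dynamics over time. Passing round trips therefore
demonstrate that the estimators are correct and well-calibrated under
the stated noise models, not that the pipeline is robust to every
artifact of in vivo data; that robustness is exactly what the original
experiments' quality control (anesthesia, holders, visual inspection)
addressed upstream of computation.
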