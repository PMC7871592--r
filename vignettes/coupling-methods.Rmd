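---
title: "Inter-regional LFP coupling metrics: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inter-regional LFP coupling metrics: models, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lfpcoupling)
```

`lfpcoupling` implements the standard battery of directed and
non-directed coupling metrics used to quantify functional connectivity
between brain regions from multi-channel local field potential (LFP)
recordings — multitaper coherence and its phase angle, the debiased
weighted phase-lag index (wPLI), phase-locking value (PLV), pairwise
phase consistency (PPC), parametric and non-parametric spectral Granger
causality (GC), partial directed coherence (PDC), the directed transfer
function (DTF), the Kullback-Leibler phase-amplitude modulation index
(MI), envelope cross-correlation lead/lag, and multi-unit spike-phase
coupling — together with a synthetic generator that plants known coupling
so every metric can be validated against ground truth. That benchmarking
step is the package's reason to exist: these metrics are routinely
applied to in-vivo data where the true coupling is unknowable, so their
estimators are exercised here on signals where it is known exactly.

## Processing paths and preprocessing

Two processing paths mirror common acquisition practice: a 1 kHz LFP
stream for spectral, phase and amplitude metrics, and a wideband
(10 kHz) stream for multi-unit extraction, with autoregressive (GC)
modelling performed at 250 Hz. Granger-causal fits consume
*unfiltered* data — band-pass filtering before VAR fitting inflates the
model order and corrupts the spectral decomposition — so the pipeline
orders re-referencing and resampling before, and band filtering after,
the directed branch splits off.

Low-frequency drift is removed by local linear detrending: a
least-squares line per 1-s sliding window, stepped by 0.5 s, blended
across windows by triangular overlap weights. A pure ramp is annihilated
and an 8 Hz oscillation passes with under 5% RMS distortion.

Band-pass filtering uses zero-phase (two-pass) FIR filters. The filter
order is sized so the transition band does not exceed the smaller of the
band's low edge and half its width; this matters for envelope metrics,
because an amplitude-modulated carrier has sidebands offset from the
carrier by the modulation frequency, and a shallow filter skirt
attenuates them and compresses the recovered envelope (we observed
MI biases of ~35% with a 3-cycle filter before adopting this rule).
Canonical bands are delta 1–4, theta 5–12, beta 15–30 and low gamma
30–48 Hz.

Analytic signals come from the FFT Hilbert transform; the phase
convention is 0 at the positive peak of a cosine-aligned oscillation.
Resampling to an integer factor uses a sharp zero-phase FIR anti-alias
filter (cutoff 0.9 of the target Nyquist) followed by decimation;
in-band amplitudes survive to within 1%.

## Spectral estimation

Power and coherence use the multitaper method with Slepian (DPSS)
tapers computed from the symmetric tridiagonal eigenproblem; for windows
longer than 2048 samples the tapers are computed at a base length and
spline-interpolated, the standard large-N shortcut. Session-long spectra
default to a 0.2 Hz half-bandwidth with 220 tapers; binned spectra (10-s
bins) use 1 Hz and 19 tapers. Both satisfy K ≤ 2TW − 1. Power is
reported as 10·log10 over 0.1–48 Hz; coherence is |Sxy|/sqrt(Sxx·Syy)
with tapers (and windows) averaged in the cross-spectrum *before*
normalization, and its phase is arg(Sxy) in degrees (positive phase:
first channel leads). Band aggregates carry mean, peak and peak
frequency; theta comparisons conventionally use the peak rather than the
mean.

## Phase synchronization

wPLI/PLV/PPC operate on per-segment cross-spectra from non-overlapping
1-s windows, mean-removed, Hann-tapered and zero-padded to the next
power of two. A note on the taper: a single Hann window has no
independent smoothing parameter, so "Hann with 0.5 Hz smoothing" is not
a complete specification; we default to the single Hann taper and expose
a DPSS variant (±0.5 Hz) behind `taper = "dpss"`, claiming neither as
anyone's exact configuration.

The debiased wPLI-square estimator is
(Σ_{j<k} Im X_j · Im X_k) / (Σ_{j<k} |Im X_j|·|Im X_k|), computed by the
sum trick ((ΣIm)² − ΣIm²)/((Σ|Im|)² − ΣIm²) and verified against the
O(n²) pairwise loop to 1e−12. Its defining property — and the reason it
exists — is blindness to zero-lag mixing: a common source reaching two
electrodes instantaneously (volume conduction) produces a purely real
cross-spectrum, so wPLI sits at its noise floor while coherence
saturates near 1. The 0/0 case is defined as 0, and negative values are
reported as-is; clipping would reintroduce the bias the estimator
removes. PPC is the sample-size-unbiased counterpart of PLV,
algebraically (n·PLV² − 1)/(n − 1); the identity is enforced exactly,
and the null contrast (PPC mean ≈ 0 vs PLV bias ~1/√n) is tested.

## Directed metrics

VAR models are fitted by pooled least squares over 10-s sections (rows
crossing a section boundary are excluded), with BIC order selection and
a stability check on the companion-matrix spectral radius. Spectral GC
uses Geweke's decomposition with the full noise-correlation rotation
H̃ = H_yx + (Σ_xy/Σ_xx)H_yy — the plain textbook form is only valid for
diagonal innovation covariance. Band values are means over in-band
frequency bins (a trapezoid option exists); any log10 scaling is applied
at reporting time only.

Non-parametric GC factorizes a multitaper cross-spectral matrix by
Wilson's algorithm into a minimum-phase transfer function and innovation
covariance, then applies the same Geweke formula. Two numerical points:
(1) the cross-spectral estimate must be zero-padded (factor 2) — the
unpadded grid cannot hold the full autocovariance support and the
factorization stalls at a ~5e−4 residual floor from wrap-around
aliasing; (2) for estimated (noisy) spectra the residual converges to a
sampling-noise floor rather than to zero, so the iteration stops on
stagnation (relative improvement < 1e−3 per step) and errors only above
1e−3 residual. On analytic spectra it reaches 1e−9 in ~30 iterations,
and npGC matches parametric GC within ~1% band-integrated.

PDC uses the original column-normalized Baccalá form on
Ā(f) = I − ΣA_k e^{−i2πfk/rate}; DTF row-normalizes H = Ā⁻¹. Both are
verified against direct evaluation of those formulas to 1e−10.

Permutation significance reassigns 10-s sections of the source channel
across time (the generic exchangeability unit for this sectioned design)
and uses p = (1 + #{perm ≥ obs})/(1 + n_perm); fewer than 19
permutations cannot resolve α = 0.05 and are refused. Type-I error
calibrates to 5% ± 2% over 200 independent-channel replicates.

## Cross-frequency coupling

The MI bins theta phase into eighteen 20° bins (bin 1 = [−180°, −160°)
in the wrapped convention), averages gamma amplitude per bin, normalizes
to a probability profile and reports KL divergence from uniform scaled
by log 18. Sessions are split into 1-min bins and the per-bin MI values
averaged. The estimator is validated against numeric quadrature of the
1 + m·cos φ envelope family at m ∈ {0.25, 0.5, 1} to within 2%, and no
surrogate or amplitude normalization is applied (matching the plain KL
formulation). Direction labels name the theta-contributing region first.

## Lead/lag estimation

Envelope cross-correlation uses 1-s windows with 95% overlap,
mean-subtracted and normalized by the windows' zero-lag energies (so
peak location is scale-free), searched over ±100 ms. Ties break toward
zero lag (bias toward the null); windows peaking on the search boundary
are excluded since their true peak may lie outside the admissible range.
Positive lag means the first-named signal leads. Pooled window lags per
recording are summarized by the median; cohort-level inference tests
per-recording medians (windows within a recording are heavily
overlapped, hence far from independent).

## Spike-phase coupling

Multi-unit activity is extracted by high-pass filtering above 800 Hz and
thresholding at mean + 3.5 SD; events supra-threshold for > 2 ms are
artifacts, and of any spike pair closer than 1 ms the second is dropped.
Spike time is the first supra-threshold sample — the simplest
reproducible convention. Note that a zero-phase high-pass reshapes long
artifacts into split sub-2-ms lobes, so the duration rule mainly catches
railing/saturation events; the rule's logic is therefore unit-tested
directly on constructed crossings as well as end-to-end.

Theta phase is defined by linear interpolation between troughs of the
5–12 Hz filtered signal (trough = 0°/360°, peak ≈ 180°), with troughs
refined to sub-sample precision by a parabolic fit — integer-sample
troughs bias the phase by ~1.4° at 1 kHz. This trough-anchored phase
tracks asymmetric (speed-dependent) theta waveforms that bias the
Hilbert phase. An amplitude gate masks samples where the Hilbert theta
envelope is weak; the customary phrasing of this gate — the amplitude
exceeding 0.25 standard deviations relative to its mean — admits two
readings, so the default is amplitude > mean + 0.25·SD with the
alternative (amplitude > 0.25·SD) behind `gate_mode = "sd_only"`, and
the choice is recorded in the output metadata. Note the default gate excludes nearly everything on a
constant-envelope test tone (its SD is tiny, so the gate sits at the
envelope's ripple); validation scenarios therefore use irregular,
amplitude-fluctuating theta.

MRL and mean angle are computed on exactly 1000 spikes subsampled
uniformly at random (seeded) from the gated spike set — fixed counts
prevent spuriously high MRL at low spike counts — and recordings with
fewer eligible spikes are excluded explicitly rather than estimated.
The offset profile recomputes MRL at spike-time shifts from −100 to
+100 ms in 4-ms steps; that range and step arithmetically give 51
offsets (not 50), and 51 are implemented. A positive best offset means
spikes lock best to the upcoming theta cycle. The von Mises benchmark
(κ = 1, n = 1000) recovers MRL within 3 SE of I₁(1)/I₀(1) ≈ 0.446 and
the planted preferred phase within 5°.

## Time courses and slopes

Each metric is evaluated in consecutive bins of its own conventional
size (10 s for power/coherence; 1 min for wPLI/PLV/PPC/MI/GC) and the
within-session change is condensed into the slope of an OLS line over
bin midpoints *in minutes* — making slopes comparable across metrics
with different bin sizes. Spike-phase slopes are not computed: the
fixed-count subsampling requires more spikes than short bins contain.

## Group statistics and redundancy

Group comparisons dispatch on metric type: Welch t for linear metrics
(the safer unequal-variance default), Watson-Williams for circular ones
(with a warning when the pooled concentration is too low for the F
approximation), and a two-factor mixed ANOVA (group × within-condition,
subject error stratum) with Sidak-adjusted pairwise contrasts for
paired-direction designs. Redundancy analysis computes Spearman
correlations between metric columns (average ranks for ties), with
Jammalamadaka–SenGupta circular–circular and Mardia circular–linear
estimators for angle-valued metrics (the specific circular estimators in
wide use; other choices exist). P-values are deliberately unadjusted —
the analysis emulates a study using a single metric at a time, and false
negatives are the greater risk when hunting redundancies. The consensus
matrix averages each metric pair's correlation over the three
connections and flags significance only when present in all of them
(α ∈ {0.01, 0.001}); the flag is monotone in α by construction.

## The synthetic generator: what it emulates and what it does not

Each generator plants one coupling mechanism with known parameters:
stable VAR influence (directed prediction), fixed phase lags
(coherence-phase and wPLI), zero-lag mixing (the volume-conduction
confound), theta-phase-dependent gamma envelopes (MI), von Mises
spike locking with optional uniform delay (MRL/offset), and two-group
cohorts whose coupling weight drifts linearly within the session at
group-specific slopes, with Gaussian between-subject jitter. Noise is
Gaussian, with SNR defined as a band variance ratio; VAR burn-in is
10× the model order; spike delays are applied in continuous time and
rounded to the sampling grid; one top-level seed spawns per-block
substreams deterministically, so identical scenarios are bit-identical.

The generator's cohort drift conditions were fixed once at values a
small-animal electrophysiology study could plausibly show: groups of 12
and 15 subjects (the genotype cohort sizes the analysis targets), a
coupling weight of ~0.4 against unit-variance noise of SD 0.5
(mid-range theta coherence ≈ 0.5–0.7, typical of hippocampal–prefrontal
pairs), a drift of 0.4 weight-units per minute for the drifting group,
and 0.05 between-subject jitter. No published effect sizes exist for
these synthetic parameters — they are free by construction — so they
are documented here and not revisited.

What the generator does *not* emulate: 1/f background with realistic
spectral exponents, non-sinusoidal oscillation shape beyond the
frequency-jittered theta used in spike-phase scenarios, nonstationary
noise variance, behavioural state changes, electrode drift, or
artifacts. Passing the benchmark therefore demonstrates estimator
correctness under each metric's own model assumptions — not robustness
to everything real recordings contain.

## Problem sizes

Validation runs use deliberately compact scenarios: 20–60 s records at
200–1000 Hz (250 Hz for VAR work), 100 seeds for direction-ratio
recovery, 200 replicates for permutation calibration, 500 for the
scalar test calibrations, 20 for consensus recovery, and 1-s analysis
windows for the Wilson factorization input. These sizes put every
Monte-Carlo standard error well inside the asserted tolerance bands
while keeping the full suite fast; all sizes are parameters, and larger
runs only tighten the bands.

## Known limitations

Pairwise (not conditional) GC only, so a common driver of both channels
can produce spurious bidirectional influence; the Watson-Williams
approximation degrades at low concentration (it warns); the
Jammalamadaka circular correlation p-value is asymptotic; the wPLI
windowing convention ("Hann with 0.5 Hz smoothing") is ambiguous at the
source and both readings are provided; the 50-vs-51 offset count in the
spike-offset grid is resolved in favour of the arithmetic (51); and the
HDF5/TOML interchange formats some toolchains use are replaced by CSV,
YAML and JSON throughout.
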