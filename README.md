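# lfpcoupling

Directed and non-directed coupling metrics for multi-channel local
field potential (LFP) recordings, with a ground-truth simulator to
benchmark every one of them.

Neuroscience studies routinely quantify "functional connectivity"
between brain regions (e.g. prefrontal cortex and hippocampus) with a
zoo of metrics — coherence, weighted phase-lag index (wPLI),
phase-locking value (PLV), pairwise phase consistency (PPC), spectral
Granger causality (GC), partial directed coherence (PDC), directed
transfer function (DTF), theta–gamma modulation index (MI), envelope
lead/lag, spike–phase coupling — yet these estimators are almost never
validated against signals whose true coupling is known. This package
implements the full battery in R and pairs it with a synthetic LFP/spike
generator that plants known coupling (directed VAR influence, fixed
phase lags, zero-lag volume-conduction mixing, theta-phase-dependent
gamma envelopes, von-Mises-locked spikes, two-group cohorts with
within-session drift), so every metric can be checked against ground
truth. It is aimed at electrophysiologists and methods developers who
want connectivity estimators whose failure modes have been measured.

## The estimators at a glance

* **Multitaper spectra** (Slepian tapers; session plan 0.2 Hz × 220
  tapers, binned plan 1 Hz × 19 tapers): power `10·log10 S_xx(f)`,
  coherence `|S_xy|/√(S_xx S_yy)` and its phase `arg S_xy`.
* **Debiased wPLI**:
  `Σ_{j<k} Im X_j · Im X_k / Σ_{j<k} |Im X_j|·|Im X_k|` over 1-s
  segments — immune to zero-lag (volume-conducted) mixing.
* **PLV / PPC**: `|mean_j e^{i arg X_j}|` and its unbiased counterpart
  `(n·PLV² − 1)/(n − 1)`.
* **Spectral GC** (Geweke):
  `f_{x→y}(f) = ln S_yy / (S_yy − Σ_{xx|y} |H̃_yx|²)` from a sectioned
  VAR fit (BIC order selection), and non-parametrically from Wilson's
  spectral matrix factorization; permutation significance by section
  shuffling.
* **PDC / DTF**: column-normalized `Ā(f)` and row-normalized
  `H(f) = Ā(f)⁻¹`.
* **PAC modulation index**: KL divergence of the 18-bin phase–amplitude
  profile from uniform, scaled to [0, 1].
* **Spike–phase coupling**: MUA extraction (800 Hz high-pass, 3.5 SD
  threshold, 2-ms width and 1-ms refractory rules),
  trough-interpolated theta phase, MRL on exactly 1000 subsampled
  spikes, and the ±100 ms (4-ms step) shifted-MRL offset profile.
* **Time-course slopes** (OLS per minute) and **redundancy consensus**
  (Spearman / circular correlations averaged over connections, flagged
  only when significant in all of them).

## Worked example

Simulate 60 s of a two-channel system in which channel 1 drives
channel 2 through a stable VAR(2) (coefficient 0.4 on the lagged
cross-term), then estimate directed influence both ways:

```r
library(lfpcoupling)

A <- list(matrix(c(0.55, 0,
                   0.4,  0.55), 2, 2, byrow = TRUE),
          diag(c(-0.7, -0.7)))
rec  <- gen_var_lfp(A, diag(2), duration_s = 60, rate_hz = 250,
                    labels = c("PFC", "dHC"), seed = 1)
secs <- make_sections(n_samples(rec), 250, 10)
m    <- fit_var(rec, p = select_order(rec, 8, sections = secs),
                sections = secs)
gc   <- gc_spectrum(m)
np   <- np_gc(mt_spectral_matrix(rec, win_s = 1, nw = 3, k = 5))
perm <- gc_permutation_null(rec, m$p, n_perm = 199, seed = 7)
```

On this data the analysis driver (`analysis/03_directed.R`) prints:

```
       direction       gc gc_log10    npgc pdc_theta dtf_theta p_perm
theta   PFC->dHC 2.48e-01   -0.606 0.24627   0.34155   0.34155  0.005
theta1  dHC->PFC 8.12e-05   -4.090 0.00246   0.00173   0.00173  0.835
```

Reading: parametric GC in the planted direction (0.248) sits three
orders of magnitude above the reverse direction (8e−5, the estimation
floor), the non-parametric route agrees with the parametric one within
~1%, PDC/DTF assign the theta-band influence the same way, and the
permutation test rejects the null only for the true direction
(p = 0.005 vs 0.835).

The numbered scripts under `analysis/` walk through the full workflow —
`01_simulate.R` (datasets), `02_spectral_sync.R` (coherence vs wPLI on
volume-conducted and phase-lagged pairs), `03_directed.R` (above),
`04_pac_spikes.R` (MI and spike-phase recovery), `05_timecourse_stats.R`
(cohort slopes, group tests, redundancy consensus) — each writing its
tables under `results/`.

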