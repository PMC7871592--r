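Package: lfpcoupling
Title: Inter-Regional LFP Coupling Metrics with Ground-Truth Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Directed and non-directed coupling metrics for multi-channel
    local field potential (LFP) recordings: multitaper power, coherence and
    coherence phase; debiased weighted phase-lag index, phase-locking value
    and pairwise phase consistency; parametric spectral Granger causality
    with BIC order selection and permutation significance; non-parametric
    Granger causality via Wilson spectral matrix factorization; partial
    directed coherence and directed transfer function; cross-regional
    theta-gamma phase-amplitude coupling (Kullback-Leibler modulation
    index); envelope cross-correlation lead/lag; multi-unit spike-phase
    coupling with circular statistics; per-bin metric time courses with
    slope summaries; and a cross-metric redundancy analysis with consensus
    over connections. Includes a synthetic LFP/spike generator with known
    coupling ground truth (stable VAR influence, fixed phase lags, zero-lag
    common-source mixing, theta-gamma modulation, von-Mises-locked spikes,
    two-group cohorts with within-session drift) for benchmarking every
    metric against planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
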