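#!/usr/bin/env Rscript
# Spectral and phase-synchronization analysis of the simulated pairs.
# Finding: on the zero-lag (volume-conducted) pair, coherence saturates
# near 1 while the debiased wPLI stays at its noise floor; on the 90
# degree phase-lagged pair both coherence and wPLI respond, and the
# coherence phase angle at 8 Hz reads the planted lag.

suppressPackageStartupMessages(library(lfpcoupling))
dir.create("results", showWarnings = FALSE)

scen <- demo_scenarios()
vc <- scen$volume_conduction
pl <- scen$phase_lagged

summarize_pair <- function(rec, label) {
  co <- mt_coherence(rec, plan = taper_plan(0.5, 19))
  cs <- cross_spectra(rec)
  w <- wpli_debiased(cs)
  v <- plv(cs); p <- ppc(cs)
  i8 <- which.min(abs(co$magnitude$freqs - 8))
  data.frame(
    scenario = label,
    coherence_theta = co$magnitude$band_aggregates$theta$mean,
    phase_deg_8hz = co$phase$values[i8],
    wpli_theta = w$band_aggregates$theta$mean,
    plv_theta = v$band_aggregates$theta$mean,
    ppc_theta = p$band_aggregates$theta$mean)
}

tab <- rbind(summarize_pair(vc, "zero_lag_common_source"),
             summarize_pair(pl, "phase_lag_90deg_8hz"))
write.csv(tab, "results/02_sync_summary.csv", row.names = FALSE)
print(tab, digits = 3)

# full spectra of the lagged pair for plotting/inspection
co <- mt_coherence(pl, plan = taper_plan(0.5, 19))
spec <- data.frame(freq = signif(co$magnitude$freqs, 7),
                   coherence = signif(co$magnitude$values, 6),
                   phase_deg = signif(co$phase$values, 6))
write.csv(spec, "results/02_coherence_spectrum.csv", row.names = FALSE)
message("wrote results/02_sync_summary.csv and 02_coherence_spectrum.csv")
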