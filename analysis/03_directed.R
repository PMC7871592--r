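#!/usr/bin/env Rscript
# Directed-coupling analysis of the unidirectional VAR pair (PFC drives
# dHC by construction). Finding: parametric GC, non-parametric GC (Wilson
# factorization), PDC and DTF all assign the influence to PFC->dHC, the
# reverse direction sits at the estimation floor, and the permutation
# test rejects the null only for the true direction.

suppressPackageStartupMessages(library(lfpcoupling))
rec <- demo_scenarios()$var_directed
dir.create("results", showWarnings = FALSE)

secs <- make_sections(n_samples(rec), rec$rate_hz, 10)
p_bic <- select_order(rec, 8, sections = secs)
message("BIC order: ", p_bic)
m <- fit_var(rec, p_bic, sections = secs)

ds <- gc_spectrum(m)
npg <- np_gc(mt_spectral_matrix(rec, win_s = 1, nw = 3, k = 5))
dp <- pdc(m)
dd <- dtf(m)
perm <- gc_permutation_null(rec, p_bic, n_perm = 199, seed = 7)

rows <- do.call(rbind, lapply(c("1->2", "2->1"), function(dir_) {
  lab <- if (dir_ == "1->2") "PFC->dHC" else "dHC->PFC"
  data.frame(direction = lab,
             gc = band_integral(ds, dir_),
             gc_log10 = log10(max(band_integral(ds, dir_), 1e-12)),
             npgc = band_integral(npg, dir_),
             pdc_theta = dp$band_integrals[[dir_]]["theta"],
             dtf_theta = dd$band_integrals[[dir_]]["theta"],
             p_perm = perm$p[dir_])
}))
write.csv(rows, "results/03_directed_summary.csv", row.names = FALSE)
print(rows, digits = 3)
message("wrote results/03_directed_summary.csv")
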