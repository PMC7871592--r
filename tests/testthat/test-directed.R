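test_that("VAR fit recovers known coefficients and flags degeneracy", {
  sys <- unidir_var()
  r <- gen_var_lfp(sys$A, sys$Sigma, 60, 250, seed = 21)
  secs <- make_sections(n_samples(r), 250, 10)
  m <- fit_var(r, 2, sections = secs)
  expect_true(m$stable)
  expect_lt(sqrt(mean((unlist(m$A) - unlist(sys$A))^2)), 0.05)
  # white noise: coefficients near zero
  wn <- gen_var_lfp(list(matrix(0, 2, 2)), diag(2), 30, 250, seed = 22)
  mw <- fit_var(wn, 2)
  expect_lt(max(abs(unlist(mw$A))), 0.05)
  dup <- lfp_recording(rbind(r$data[1, ], r$data[1, ]), 250)
  expect_error(fit_var(dup, 2), "singular")
})

test_that("BIC selects the generating order and respects p_max", {
  sys <- unidir_var()
  r <- gen_var_lfp(sys$A, sys$Sigma, 60, 250, seed = 23)
  expect_equal(select_order(r, 8), 2)
  wn <- gen_var_lfp(list(matrix(0, 2, 2)), diag(2), 20, 250, seed = 24)
  expect_lte(select_order(wn, 6), 2)
  expect_equal(select_order(r, 1), 1)
  expect_error(select_order(r, 0), "p_max")
})

test_that("GC vanishes for decoupled channels and matches the closed form", {
  diagm <- structure(list(A = list(diag(c(0.5, 0.3))), Sigma = diag(2),
                          rate_hz = 250, n = 2, stable = TRUE),
                     class = "var_model")
  ds0 <- gc_spectrum(diagm)
  expect_true(all(ds0$values[["1->2"]] == 0))
  expect_true(all(ds0$values[["2->1"]] == 0))
  sys <- unidir_var()
  freqs <- seq(0, 125, length.out = 65)
  truth <- oracle_gc_12(sys$A, sys$Sigma, freqs, 250)
  r <- gen_var_lfp(sys$A, sys$Sigma, 60, 250, seed = 25)
  m <- fit_var(r, 2, sections = make_sections(n_samples(r), 250, 10))
  ds <- gc_spectrum(m, freqs)
  expect_lt(abs(mean(ds$values[["1->2"]]) / mean(truth) - 1), 0.1)
  expect_lt(mean(ds$values[["2->1"]]), 0.05 * mean(truth))
})

test_that("time reversal flips the dominant GC direction", {
  sys <- unidir_var()
  r <- gen_var_lfp(sys$A, sys$Sigma, 60, 250, seed = 26)
  secs <- make_sections(n_samples(r), 250, 10)
  fwd <- gc_spectrum(fit_var(r, 2, sections = secs))
  rev_rec <- lfp_recording(r$data[, rev(seq_len(n_samples(r)))], 250)
  bwd <- gc_spectrum(fit_var(rev_rec, 2, sections = secs))
  expect_gt(band_integral(fwd, "1->2"), band_integral(fwd, "2->1"))
  expect_gt(band_integral(bwd, "2->1"), band_integral(bwd, "1->2"))
})

test_that("Wilson factorization reconstructs S and reproduces GC", {
  sys <- unidir_var()
  tm <- true_var_model(sys)
  sm <- var_spectral_matrix(tm, freqs = seq(0, 125, length.out = 129))
  fac <- wilson_factorize(sm)
  expect_lt(fac$residual, 1e-6)
  # reconstruction at arbitrary frequencies
  for (k in c(1, 40, 129)) {
    rec <- fac$H[, , k] %*% fac$Sigma %*% Conj(t(fac$H[, , k]))
    expect_lt(max(Mod(rec - sm$S[, , k])) / max(Mod(sm$S[, , k])), 1e-6)
  }
  npg <- np_gc(sm)
  par <- gc_spectrum(tm, freqs = sm$freqs)
  expect_lt(abs(band_integral(npg, "1->2") /
                band_integral(par, "1->2") - 1), 0.05)
  expect_lt(band_integral(npg, "2->1"), 0.01)
  # diagonal S factorizes to zero npGC
  dm <- structure(list(A = list(diag(c(0.4, 0.6))), Sigma = diag(2),
                       rate_hz = 250, n = 2, stable = TRUE),
                  class = "var_model")
  smd <- var_spectral_matrix(dm, freqs = seq(0, 125, length.out = 65))
  npd <- np_gc(smd)
  expect_lt(max(npd$values[["1->2"]], npd$values[["2->1"]]), 1e-6)
})

test_that("PDC and DTF satisfy their normalization identities", {
  sys <- unidir_var()
  r <- gen_var_lfp(sys$A, sys$Sigma, 30, 250, seed = 27)
  m <- fit_var(r, 2, sections = make_sections(n_samples(r), 250, 10))
  freqs <- c(5, 10, 20, 40)
  dp <- pdc(m, freqs)
  dd <- dtf(m, freqs)
  # direct evaluation of the Fourier-transformed coefficient formula
  for (fi in seq_along(freqs)) {
    Af <- diag(2) + 0i
    for (k in 1:2) Af <- Af - m$A[[k]] * exp(-2i * pi * freqs[fi] * k / 250)
    expect_equal(dp$values[["1->2"]][fi],
                 Mod(Af[2, 1]) / sqrt(sum(Mod(Af[, 1])^2)),
                 tolerance = 1e-10)
    Hf <- solve(Af)
    expect_equal(dd$values[["1->2"]][fi],
                 Mod(Hf[2, 1]) / sqrt(sum(Mod(Hf[2, ])^2)),
                 tolerance = 1e-10)
    # column normalization of PDC: off-diagonal plus self term = 1
    self_pdc <- Mod(Af[1, 1]) / sqrt(sum(Mod(Af[, 1])^2))
    expect_equal(dp$values[["1->2"]][fi]^2 + self_pdc^2, 1,
                 tolerance = 1e-10)
  }
  # decoupled model: off-diagonal PDC/DTF are zero
  dm <- structure(list(A = list(diag(c(0.4, 0.6))), Sigma = diag(2),
                       rate_hz = 250, n = 2, stable = TRUE, p = 1),
                  class = "var_model")
  dm$n <- 2
  expect_true(all(pdc(dm, freqs)$values[["1->2"]] == 0))
  expect_true(all(dtf(dm, freqs)$values[["2->1"]] == 0))
})

test_that("permutation significance is seeded and detects true coupling", {
  sys <- unidir_var()
  r <- gen_var_lfp(sys$A, sys$Sigma, 60, 250, seed = 28)
  p1 <- gc_permutation_null(r, 2, n_perm = 49, seed = 5)
  p2 <- gc_permutation_null(r, 2, n_perm = 49, seed = 5)
  expect_identical(p1$p, p2$p)
  expect_equal(unname(p1$p["1->2"]), 1 / 50)
  expect_error(gc_permutation_null(r, 2, n_perm = 10), "n_perm")
  short <- gen_var_lfp(sys$A, sys$Sigma, 40, 250, seed = 29)
  expect_error(gc_permutation_null(short, 2, section_s = 10), "6 sections")
})
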