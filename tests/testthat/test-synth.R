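test_that("generators are bit-identical under a fixed seed", {
  sys <- unidir_var()
  r1 <- gen_var_lfp(sys$A, sys$Sigma, 5, 250, seed = 42)
  r2 <- gen_var_lfp(sys$A, sys$Sigma, 5, 250, seed = 42)
  expect_identical(r1$data, r2$data)
  p1 <- gen_phase_lagged_pair(8, 90, 5, 5, 200, seed = 7)
  p2 <- gen_phase_lagged_pair(8, 90, 5, 5, 200, seed = 7)
  expect_identical(p1$data, p2$data)
  gs <- list(a = list(n_subjects = 2, coupling = 0.5, slope = 0,
                      jitter_sd = 0.05),
             b = list(n_subjects = 2, coupling = 0.5, slope = 0.2,
                      jitter_sd = 0.05))
  c1 <- gen_cohort(gs, 10, 200, seed = 3)
  c2 <- gen_cohort(gs, 10, 200, seed = 3)
  expect_identical(c1$recordings[[4]]$data, c2$recordings[[4]]$data)
  expect_identical(c1$meta, c2$meta)
})

test_that("zero-coefficient VAR gives independent white noise", {
  r <- gen_var_lfp(list(matrix(0, 2, 2)), diag(2), 40, 250, seed = 1)
  x <- r$data[1, ]; y <- r$data[2, ]
  n <- length(x)
  # sample cross-covariance at lag 1 ~ N(0, 1/n)
  ccov1 <- mean(x[-1] * y[-n])
  expect_lt(abs(ccov1), 4 / sqrt(n))
  expect_lt(abs(cor(x, y)), 4 / sqrt(n))
})

test_that("unstable VAR is rejected with the spectral radius reported", {
  A <- list(matrix(c(1.1, 0, 0, 0.5), 2, 2))
  expect_error(gen_var_lfp(A, diag(2), 1, 100), "spectral radius 1.1")
  expect_error(gen_var_lfp(list(matrix(0, 2, 2)),
                           matrix(c(1, 2, 2, 1), 2, 2), 1, 100),
               "positive definite")
})

test_that("phase-lagged pair carries the requested lag and rejects bad f", {
  expect_error(gen_phase_lagged_pair(120, 0, 1, 1, 200), "Nyquist")
  r <- gen_phase_lagged_pair(8, 90, Inf, 10, 256, seed = 1)
  # noise-free: channel 2 is channel 1 shifted a quarter cycle of 8 Hz
  shift <- 256 / 8 / 4  # exactly 8 samples at 256 Hz
  nt <- n_samples(r)
  # channel 2 lags: data2[n] = data1[n - shift]
  expect_lt(max(abs(r$data[2, (shift + 1):nt] -
                    r$data[1, 1:(nt - shift)])), 1e-9)
})

test_that("common-source mixing yields the predicted cross-spectrum", {
  set.seed(5)
  nt <- 4000; rate <- 200
  src <- rbind(lfpcoupling:::fir_bandpass(rnorm(nt), 4, 30, rate),
               lfpcoupling:::fir_bandpass(rnorm(nt), 4, 30, rate))
  M <- matrix(c(1, 0.5, 0.3, 1), 2, 2)
  r <- gen_common_source(M, src, rate_hz = rate, seed = 2)
  expect_equal(r$data, M %*% src)
  # predicted channel cross-spectrum M S_src M^H against the estimate
  sm_src <- mt_spectral_matrix(lfp_recording(src, rate), win_s = 2)
  sm_out <- mt_spectral_matrix(r, win_s = 2)
  sel <- which(sm_src$freqs >= 8 & sm_src$freqs <= 20)
  pred <- sapply(sel, function(k) M %*% sm_src$S[, , k] %*% t(M))
  est <- sapply(sel, function(k) sm_out$S[, , k])
  expect_lt(max(Mod(pred - est)) / max(Mod(pred)), 1e-10)
  expect_error(gen_common_source(matrix(c(1, NA), 2, 1), src[1, ],
                                 rate_hz = rate), "finite")
})

test_that("pac generator validates inputs and encodes the planted depth", {
  expect_error(gen_pac_signal(8, 60, 1.5, 1, 500), "\\[0, 1\\]")
  expect_error(gen_pac_signal(8, 14, 0.5, 1, 500), "f_gamma")
  r <- gen_pac_signal(8, 60, 0.5, 2, 500, seed = 1)
  t <- (seq_len(n_samples(r)) - 1) / 500
  env <- 1 + 0.5 * cos(2 * pi * 8 * t)
  # noise-free channel B has |B| <= envelope with equality at carrier peaks
  expect_true(all(abs(r$data[2, ]) <= env + 1e-12))
})

test_that("locked spikes match their von Mises target concentration", {
  rate <- 1000; t <- (0:119999) / rate
  ph <- lfpcoupling:::wrap_pi(2 * pi * 8 * t)
  # kappa -> inf: all phases at mu
  s_inf <- gen_locked_spikes(ph, rate, 90, 1e9, 200, seed = 1)
  idx <- round(s_inf$times * rate) + 1
  ang <- ph[idx]
  rv <- circ_resultant(ang)
  expect_gt(rv$r, 0.999)
  expect_lt(abs(wrapd(rv$mu * 180 / pi - 90)), 2)
  # kappa = 0: uniform, MRL ~ 1/sqrt(n)
  s0 <- gen_locked_spikes(ph, rate, 90, 0, 1000, seed = 2)
  ang0 <- ph[round(s0$times * rate) + 1]
  expect_lt(circ_resultant(ang0)$r, 0.1)
  # kappa = 1: MRL near I1(1)/I0(1), within 3 SE (SE from a quick
  # Monte-Carlo of the resultant of 1000 von Mises draws)
  bessel_ratio <- besselI(1, 1) / besselI(1, 0)
  se <- sd(replicate(40, {
    z <- rvonmises(1000, 0, 1); Mod(mean(exp(1i * z)))
  }))
  s1 <- gen_locked_spikes(ph, rate, 90, 1, 1000, seed = 3)
  ang1 <- ph[round(s1$times * rate) + 1]
  expect_lt(abs(circ_resultant(ang1)$r - bessel_ratio), 3 * se)
  expect_error(gen_locked_spikes(ph[1:50], rate, 0, 1, 10), "too short")
})

test_that("cohort generator enforces group sizes and plants drift", {
  gs_bad <- list(a = list(n_subjects = 1, coupling = 0.5, slope = 0,
                          jitter_sd = 0))
  expect_error(gen_cohort(gs_bad), ">= 2 subjects")
  gs <- list(flat = list(n_subjects = 2, coupling = 0.6, slope = 0,
                         jitter_sd = 0.02),
             ramp = list(n_subjects = 2, coupling = 0.3, slope = 0.4,
                         jitter_sd = 0.02))
  co <- gen_cohort(gs, duration_s = 60, rate_hz = 200, seed = 11)
  expect_length(co$recordings, 4)
  expect_equal(co$meta$group, c("flat", "flat", "ramp", "ramp"))
  expect_equal(co$meta$slope, c(0, 0, 0.4, 0.4))
})
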