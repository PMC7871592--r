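test_that("threshold crossing rules: width exclusion and refractory period", {
  expect_equal(extract_mua(rep(0, 50000), 10000)$n, 0)
  rt <- 10000
  x <- numeric(rt)  # 1 s of silence with constructed crossings
  x[1001:1005] <- 1        # 0.5 ms event: a spike
  x[3001:3030] <- 1        # 3 ms supra-threshold event: artifact
  x[5001:5003] <- 1        # spike ...
  x[5008:5010] <- 1        # ... followed 0.7 ms later: refractory drop
  x[7001:7003] <- 1        # spike ...
  x[7021:7023] <- 1        # ... followed 2 ms later: kept
  times <- lfpcoupling:::threshold_spike_times(x, 0.5, rt)
  expect_equal(times, c(0.1, 0.5, 0.7, 0.702))
})

test_that("injected 6-SD waveforms are detected within 1 ms", {
  set.seed(52)
  rt <- 10000; dur <- 20
  sig <- rnorm(dur * rt)
  spk <- sort(sample(seq(5000, dur * rt - 5000, by = 40), 200))
  tt <- (-15:15) / rt
  wave <- 6 * exp(-(tt / 2e-4)^2) * cos(2 * pi * 2500 * tt)
  for (s in spk) sig[s + (-15:15)] <- sig[s + (-15:15)] + wave
  mua <- extract_mua(sig, rt)
  hit <- vapply(spk / rt, function(ts) any(abs(mua$times - ts) <= 0.001),
                logical(1))
  expect_gte(mean(hit), 0.95)
  # re-detection on a reconstruction finds the same times (idempotence)
  recon <- numeric(dur * rt)
  for (s in round(mua$times * rt) + 1)
    recon[s + (-15:15)] <- recon[s + (-15:15)] + wave
  mua2 <- extract_mua(recon + 0.01 * rnorm(dur * rt), rt)
  matched <- vapply(mua$times, function(ts)
    any(abs(mua2$times - ts) <= 0.0005), logical(1))
  expect_gt(mean(matched), 0.95)
})

test_that("trough-interpolated phase matches the analytic phase of a tone", {
  rate <- 1000; t <- (0:59999) / rate
  tps <- theta_phase_interp(lfp_recording(cos(2 * pi * 8 * t), rate))
  # trough convention: phase 0 at the trough, so analytic cosine phase + 180
  ana <- (8 * 360 * t + 180) %% 360
  mid <- 5000:55000
  err <- abs(wrapd(tps$phase_deg[mid] - ana[mid]))
  expect_lt(max(err, na.rm = TRUE), 1)
  expect_error(theta_phase_interp(lfp_recording(rep(0, 3000), 1000)),
               "troughs")
})

test_that("the amplitude gate masks silent gaps", {
  rate <- 1000; t <- (0:39999) / rate
  amp_mod <- rep(1, length(t)); amp_mod[10000:20000] <- 0.02
  x <- amp_mod * cos(2 * pi * 8 * t)
  tps <- theta_phase_interp(lfp_recording(x, rate))
  expect_lt(mean(tps$valid[12000:18000]), 0.05)
  expect_gt(mean(tps$valid[25000:35000]), 0.5)
})

test_that("MRL and mean angle behave at the defined extremes", {
  rate <- 1000; t <- (0:119999) / rate
  rec <- gen_irregular_theta(120000, rate, 53)
  tps <- theta_phase_interp(rec, gate_mode = "sd_only")
  phr <- lfpcoupling:::wrap_pi(tps$phase_deg * pi / 180)
  # highly concentrated spikes: MRL ~ 1 at mu
  sp <- gen_locked_spikes(phr, rate, 90, 500, 2500, seed = 1)
  res <- spike_phase_coupling(sp, tps, n_fix = 1000, seed = 2)
  expect_equal(res$status, "ok")
  expect_gt(res$mrl, 0.98)
  expect_lt(abs(wrapd(res$mean_angle_deg - 90)), 5)
  # four equally spaced phases, equal counts -> MRL 0
  ph4 <- c(0, 90, 180, 270) * pi / 180
  rv <- circ_resultant(rep(ph4, 250))
  expect_lt(rv$r, 1e-12)
  # too few eligible spikes -> explicit exclusion
  few <- gen_locked_spikes(phr, rate, 0, 1, 200, seed = 3)
  resx <- spike_phase_coupling(few, tps, n_fix = 1000, seed = 2)
  expect_equal(resx$status, "excluded")
  expect_true(is.na(resx$mrl))
})

test_that("MRL is rotation-invariant; subsampling is seed-reproducible", {
  set.seed(54)
  ph <- rvonmises(1500, 0.3, 2)
  r0 <- circ_resultant(ph)
  r1 <- circ_resultant(lfpcoupling:::wrap_pi(ph + 1.1))
  expect_equal(r0$r, r1$r, tolerance = 1e-12)
  expect_lt(abs(lfpcoupling:::wrap_pi(r1$mu - r0$mu - 1.1)), 1e-10)
  rate <- 1000
  rec <- gen_irregular_theta(60000, rate, 55)
  tps <- theta_phase_interp(rec, gate_mode = "sd_only")
  phr <- lfpcoupling:::wrap_pi(tps$phase_deg * pi / 180)
  sp <- gen_locked_spikes(phr, rate, 45, 1.5, 2000, seed = 4)
  a <- spike_phase_coupling(sp, tps, n_fix = 1000, seed = 9)
  b <- spike_phase_coupling(sp, tps, n_fix = 1000, seed = 9)
  expect_identical(a$mrl, b$mrl)
})

test_that("shifted MRL recovers a planted spike delay on the 4-ms grid", {
  rate <- 1000
  rec <- gen_irregular_theta(120000, rate, 56)
  tps <- theta_phase_interp(rec, gate_mode = "sd_only")
  phr <- lfpcoupling:::wrap_pi(tps$phase_deg * pi / 180)
  sp0 <- gen_locked_spikes(phr, rate, 90, 3, 4000, seed = 5)
  sh0 <- shifted_mrl(sp0, tps, n_fix = 1000, seed = 6)
  expect_length(sh0$mrl, 51)
  expect_lte(abs(sh0$best_offset_ms), 4)
  spd <- gen_locked_spikes(phr, rate, 90, 3, 4000, delay_ms = 24, seed = 5)
  shd <- shifted_mrl(spd, tps, n_fix = 1000, seed = 6)
  # locking is recovered when the offset cancels the +24 ms delay
  expect_lte(abs(shd$best_offset_ms + 24), 4)
})

test_that("Watson-Williams separates shifted groups and not identical ones", {
  set.seed(57)
  a <- rvonmises(15, 0, 2)
  ww_same <- watson_williams(a, a)
  expect_lt(ww_same$F, 1e-10)
  expect_gt(ww_same$p, 0.99)
  b <- rvonmises(15, pi / 2, 2)
  expect_lt(watson_williams(a, b)$p, 0.05)
  expect_error(watson_williams(a, a[1]), "2 angles")
})
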