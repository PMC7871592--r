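test_that("local detrending removes ramps and constants, passes theta", {
  rate <- 200; t <- (0:3999) / rate
  ramp <- lfp_recording(2 + 3 * t, rate)
  out <- detrend_local(ramp)
  interior <- 200:3800
  expect_lt(max(abs(out$data[1, interior])), 1e-6 * max(abs(ramp$data)))
  const <- detrend_local(lfp_recording(rep(5, 4000), rate))
  expect_lt(max(abs(const$data)), 1e-9)
  sine <- sin(2 * pi * 8 * t)
  outs <- detrend_local(lfp_recording(sine, rate))
  rel_rms <- sqrt(mean((outs$data[1, interior] - sine[interior])^2)) /
    sqrt(mean(sine[interior]^2))
  expect_lt(rel_rms, 0.05)
  # idempotence up to tolerance
  twice <- detrend_local(outs)
  expect_lt(max(abs(twice$data[1, interior] - outs$data[1, interior])),
            0.02 * sd(sine))
  expect_error(detrend_local(lfp_recording(1:10, 200), window_s = 1), "longer")
})

test_that("resampling preserves in-band amplitude and refuses upsampling", {
  rate <- 10000; t <- (0:(rate * 4 - 1)) / rate
  r8 <- lfp_recording(sin(2 * pi * 8 * t), rate)
  d <- resample_recording(r8, 1000)
  expect_equal(d$rate_hz, 1000)
  mid <- 500:(n_samples(d) - 500)
  amp <- max(abs(d$data[1, mid]))
  expect_lt(abs(amp - 1), 0.01)
  r40 <- lfp_recording(sin(2 * pi * 40 * t), rate)
  d40 <- resample_recording(r40, 250)
  amp40 <- max(abs(d40$data[1, 100:(n_samples(d40) - 100)]))
  expect_lt(abs(amp40 - 1), 0.01)
  expect_identical(resample_recording(r8, rate), r8)
  expect_error(resample_recording(r8, 2 * rate), "upsampling")
})

test_that("re-referencing is exact and involutive", {
  set.seed(2)
  x <- rnorm(500); y <- rnorm(500); c0 <- rnorm(500)
  rec <- lfp_recording(rbind(x + c0, y + c0), 100, c("A", "B"))
  clean <- rereference(rec, c0)
  expect_equal(clean$data, rbind(x, y), ignore_attr = TRUE)
  expect_equal(clean$reference, "rereferenced")
  ident <- rereference(rec, rep(0, 500))
  expect_equal(ident$data, rec$data)
  # rereference(rereference(x, r), -r) restores the input
  back <- rereference(rereference(rec, c0), -c0)
  expect_equal(back$data, rec$data)
  expect_error(rereference(rec, c0[1:10]), "length")
})

test_that("band-passed analytic signal recovers amplitude and phase rate", {
  rate <- 500; t <- (0:(20 * rate - 1)) / rate
  rec <- lfp_recording(3.2 * sin(2 * pi * 8 * t), rate)
  a <- bandpass_analytic(rec, band_spec("theta", 5, 12))
  mid <- (2 * rate):(18 * rate)
  expect_lt(max(abs(a$amplitude[mid] - 3.2)) / 3.2, 0.02)
  # phase advances at 2 pi f rad/s
  dph <- diff(a$phase[mid])
  dph <- dph[abs(dph) < pi]
  expect_lt(abs(mean(dph) * rate / (2 * pi) - 8), 0.05)
  dc <- bandpass_analytic(lfp_recording(rep(2, 4000), rate),
                          band_spec("theta", 5, 12))
  expect_lt(max(dc$amplitude[500:3500]), 0.01)
  expect_error(bandpass_analytic(rec, band_spec("hi", 100, 400)), "Nyquist")
})

test_that("segmentation counts are exact and windows stay in bounds", {
  rec <- lfp_recording(numeric(600 * 1000), 1000)
  s <- segment_windows(rec, 1, 0, pad_pow2 = TRUE)
  expect_length(s$starts, 600)
  expect_equal(s$len, 1000L)
  expect_equal(s$pad_to, 1024L)
  s95 <- segment_windows(lfp_recording(numeric(10 * 1000), 1000), 1, 0.95)
  expect_length(s95$starts, 181)  # floor((10-1)/0.05)+1
  expect_true(all(s95$starts + s95$len <= 10 * 1000))
  one <- segment_windows(lfp_recording(numeric(500), 100), 5, 0)
  expect_length(one$starts, 1)
  expect_error(segment_windows(lfp_recording(numeric(50), 100), 1), "fits")
  expect_error(segment_windows(rec, 1, 1), "overlap")
})
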