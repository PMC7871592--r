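# Preprocessing shared by all metrics: local detrending, resampling,
# re-referencing, band filtering + analytic signal, segmentation.

#' Local (sliding-window) linear detrending
#'
#' Removes a piecewise-linear local trend from each channel: a least-squares
#' line is fitted in sliding windows and the overlapping fits are blended by
#' triangular overlap weighting, mirroring locdetrend-style drift removal.
#' Oscillations at and above ~1/window_s Hz pass essentially unchanged.
#'
#' @param rec an `lfp_recording`.
#' @param window_s fit window length in seconds (default 1).
#' @param step_s window step in seconds (default 0.5).
#' @return the detrended `lfp_recording`.
#' @export
detrend_local <- function(rec, window_s = 1.0, step_s = 0.5) {
  n <- n_samples(rec)
  wl <- round(window_s * rec$rate_hz)
  st <- max(1L, round(step_s * rec$rate_hz))
  if (wl < 2) stop("window too short: fewer than 2 samples")
  if (wl > n) stop("detrend window longer than the record")
  starts <- seq.int(1L, n - wl + 1L, by = st)
  if (starts[length(starts)] + wl - 1L < n)
    starts <- c(starts, n - wl + 1L)  # cover the tail
  tt <- seq_len(wl)
  tc <- tt - mean(tt)
  sxx <- sum(tc^2)
  # triangular weight peaks at window centre; blended trends sum smoothly
  w <- pmin(tt, rev(tt))
  out <- rec$data
  for (ch in seq_len(nrow(out))) {
    x <- rec$data[ch, ]
    trend <- numeric(n)
    wsum <- numeric(n)
    for (s in starts) {
      idx <- s:(s + wl - 1L)
      seg <- x[idx]
      b <- sum(tc * seg) / sxx
      fit <- mean(seg) + b * tc
      trend[idx] <- trend[idx] + w * fit
      wsum[idx] <- wsum[idx] + w
    }
    out[ch, ] <- x - trend / wsum
  }
  lfp_recording(out, rec$rate_hz, rec$labels, rec$reference)
}

#' Anti-aliased resampling
#'
#' Polyphase resampling to a lower rate. Upsampling is refused: the pipeline
#' only ever moves from the acquisition rate down to the analysis rates.
#'
#' @param rec an `lfp_recording`.
#' @param target_hz requested output rate (<= rec$rate_hz).
#' @return resampled `lfp_recording`.
#' @export
resample_recording <- function(rec, target_hz) {
  if (target_hz > rec$rate_hz) stop("upsampling not supported")
  if (target_hz == rec$rate_hz) return(rec)
  fac <- rec$rate_hz / target_hz
  if (abs(fac - round(fac)) < 1e-9) {
    # integer decimation: sharp zero-phase FIR anti-alias then subsample
    fac <- round(fac)
    ord <- min(20L * fac, ncol(rec$data) %/% 3 - 1L)
    ord <- max(ord - ord %% 2L, 4L)
    b <- signal::fir1(ord, 0.9 / fac, type = "low")
    out <- t(apply(rec$data, 1L, function(x) {
      y <- as.numeric(signal::filtfilt(b, x))
      y[seq.int(1L, length(y), by = fac)]
    }))
  } else {
    pq <- ratio_approx(target_hz / rec$rate_hz)
    out <- t(apply(rec$data, 1L, function(x)
      as.numeric(signal::resample(x, pq[1L], pq[2L]))))
  }
  if (nrow(rec$data) == 1L) out <- matrix(out, nrow = 1L)
  lfp_recording(out, target_hz, rec$labels, rec$reference)
}

# small rational approximation p/q of a rate ratio
ratio_approx <- function(x, max_den = 10000L) {
  for (q in seq_len(max_den)) {
    p <- x * q
    if (abs(p - round(p)) < 1e-9) return(c(round(p), q))
  }
  stop("rate ratio has no small rational form")
}

#' Digital re-referencing
#'
#' Subtracts a reference trace from every channel (offline re-referencing,
#' e.g. to a frontal screw instead of the cerebellar ground).
#'
#' @param rec an `lfp_recording`.
#' @param ref_trace numeric vector, same length as the record.
#' @param ref_label label describing the new reference.
#' @return the re-referenced recording.
#' @export
rereference <- function(rec, ref_trace, ref_label = "rereferenced") {
  if (length(ref_trace) != n_samples(rec))
    stop("reference trace length does not match the recording")
  out <- sweep(rec$data, 2L, ref_trace, "-")
  lfp_recording(out, rec$rate_hz, rec$labels, ref_label)
}

# Zero-phase FIR band-pass. Order sized so the transition band stays
# inside a quarter of the band's low edge or half its width, whichever is
# narrower: amplitude-modulation sidebands near the band edges must pass
# unattenuated or envelope metrics are biased. Two-pass filtering
# (filtfilt) keeps phase estimates unbiased.
fir_bandpass <- function(x, lo, hi, rate) {
  nyq <- rate / 2
  if (hi >= nyq) stop("band edge at or above Nyquist")
  tw <- min(lo, (hi - lo) / 2)
  ord <- min(ceiling(3.3 * rate / tw), length(x) %/% 3 - 1L)
  ord <- max(ord - ord %% 2L, 4L)  # even order
  b <- signal::fir1(ord, c(lo, hi) / nyq, type = "pass")
  as.numeric(signal::filtfilt(b, x))
}

fir_highpass <- function(x, lo, rate) {
  nyq <- rate / 2
  ord <- min(3 * round(rate / lo), length(x) %/% 3 - 1L)
  ord <- max(ord - ord %% 2L, 4L)
  b <- signal::fir1(ord, lo / nyq, type = "high")
  as.numeric(signal::filtfilt(b, x))
}

# Analytic signal by frequency-domain Hilbert transform.
analytic_fft <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Band-pass filtering and analytic-signal extraction
#'
#' Zero-phase FIR band-pass followed by the Hilbert transform; returns the
#' instantaneous envelope and phase. Phase 0 sits at the positive peak of a
#' cosine-aligned oscillation (the `cos(phi)` convention).
#'
#' @param rec an `lfp_recording` (single channel used).
#' @param band a `band_spec`.
#' @param chan which channel (label or index, default first).
#' @return an `analytic_signal`.
#' @export
bandpass_analytic <- function(rec, band, chan = 1L) {
  if (!inherits(rec, "lfp_recording")) stop("rec must be an lfp_recording")
  rate <- rec$rate_hz
  x <- channel(rec, chan)
  if (band$hi >= rate / 2) stop("band extends to or beyond Nyquist")
  xf <- fir_bandpass(x, band$lo, band$hi, rate)
  z <- analytic_fft(xf)
  analytic_signal(Mod(z), Arg(z), band, rate)
}

#' Fixed-length segmentation
#'
#' Maximal set of equal-length windows fitting the record; a trailing
#' partial window is dropped. Windows are half-open `[start, start+len)`
#' in 0-based samples.
#'
#' @param rec an `lfp_recording` (or a sample count).
#' @param win_s window length in seconds.
#' @param overlap_frac fraction of overlap in `[0, 1)`.
#' @param pad_pow2 if TRUE, `pad_to` is the next power of two >= window.
#' @return a `segment_set`: list with `starts` (0-based), `len`, `pad_to`.
#' @export
segment_windows <- function(rec, win_s, overlap_frac = 0, pad_pow2 = FALSE) {
  n <- if (inherits(rec, "lfp_recording")) n_samples(rec) else as.integer(rec)
  rate <- if (inherits(rec, "lfp_recording")) rec$rate_hz else
    stop("pass an lfp_recording or use segment_samples")
  len <- round(win_s * rate)
  if (len < 2) stop("window shorter than 2 samples")
  if (overlap_frac < 0 || overlap_frac >= 1) stop("overlap must be in [0, 1)")
  step <- max(1L, round(len * (1 - overlap_frac)))
  if (len > n) stop("no window fits the record")
  starts <- seq.int(0L, n - len, by = step)
  pad_to <- if (pad_pow2) 2L^ceiling(log2(len)) else len
  structure(list(starts = as.integer(starts), len = as.integer(len),
                 pad_to = as.integer(pad_to), rate_hz = rate,
                 overlap_frac = overlap_frac),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set> %d windows of %d samples (pad to %d), step %d\n",
              length(x$starts), x$len, x$pad_to,
              if (length(x$starts) > 1) x$starts[2] - x$starts[1] else x$len))
  invisible(x)
}
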