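# Multitaper power / coherence / coherence phase.
# DPSS (Slepian) tapers are computed from the symmetric tridiagonal
# eigenproblem; for long windows they are computed at a base length and
# spline-interpolated, the standard large-N shortcut.

.dpss_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' @param n window length in samples.
#' @param nw time-half-bandwidth product (W expressed in cycles: n * W_norm).
#' @param k number of tapers (k <= 2*nw - 1 recommended).
#' @return n x k matrix; columns unit-energy, first taper positive-summed.
#' @export
dpss_tapers <- function(n, nw, k) {
  key <- sprintf("%d_%g_%d", n, nw, k)
  if (!is.null(.dpss_cache[[key]])) return(.dpss_cache[[key]])
  base_n <- 1024L
  if (n <= 2L * base_n) {
    tp <- dpss_exact(n, nw, k)
  } else {
    # interpolate from a shorter exact solution; renormalize to unit energy
    tb <- dpss_exact(base_n, nw, k)
    xb <- seq(0, 1, length.out = base_n)
    xo <- seq(0, 1, length.out = n)
    tp <- apply(tb, 2L, function(col) stats::spline(xb, col, xout = xo)$y)
    tp <- sweep(tp, 2L, sqrt(colSums(tp^2)), "/")
  }
  .dpss_cache[[key]] <- tp
  tp
}

dpss_exact <- function(n, nw, k) {
  w <- nw / n
  i <- seq_len(n) - 1
  diag_el <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  off <- i[-1] * (n - i[-1]) / 2
  M <- diag(diag_el)
  M[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  M[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  ev <- eigen(M, symmetric = TRUE)
  tp <- ev$vectors[, seq_len(k), drop = FALSE]
  # sign convention: symmetric tapers sum positive, antisymmetric start positive
  for (j in seq_len(k)) {
    s <- sum(tp[, j])
    if (abs(s) > 1e-8) {
      if (s < 0) tp[, j] <- -tp[, j]
    } else if (tp[2, j] < 0) tp[, j] <- -tp[, j]
  }
  tp
}

#' Multitaper analysis plan
#'
#' @param bandwidth_hz spectral half-bandwidth W in Hz.
#' @param n_tapers number of Slepian tapers K; must satisfy
#'   `K <= 2 * window_s * bandwidth_hz - 1`.
#' @param window_s analysis window in seconds (NULL = whole record).
#' @return a `taper_plan`.
#' @export
taper_plan <- function(bandwidth_hz, n_tapers, window_s = NULL) {
  if (n_tapers < 1) stop("need at least one taper")
  if (!is.null(window_s) && n_tapers > 2 * window_s * bandwidth_hz - 1)
    stop("n_tapers exceeds 2*T*W - 1 for this window")
  structure(list(bandwidth_hz = bandwidth_hz, n_tapers = n_tapers,
                 window_s = window_s),
            class = "taper_plan")
}

#' Session-long and binned default plans
#'
#' The session plan uses a 0.2 Hz bandwidth with 220 tapers over the whole
#' record; the binned plan uses 1 Hz with 19 tapers over 10-s bins.
#' @return a `taper_plan`.
#' @export
plan_session <- function() taper_plan(0.2, 220)

#' @rdname plan_session
#' @export
plan_binned <- function() taper_plan(1, 19, window_s = 10)

# tapered FFTs of one window: returns (nfreq x k) complex matrix + freqs
mt_fft <- function(x, rate, plan, fmin = 0.1, fmax = 48) {
  n <- length(x)
  T_s <- n / rate
  k <- plan$n_tapers
  kmax <- floor(2 * T_s * plan$bandwidth_hz - 1)
  if (k > kmax)
    stop(sprintf("window of %.3g s supports at most %d tapers at W = %g Hz",
                 T_s, kmax, plan$bandwidth_hz))
  tp <- dpss_tapers(n, T_s * plan$bandwidth_hz, k)
  nfft <- 2L^ceiling(log2(n))
  freqs <- (0:(nfft / 2)) * rate / nfft
  xt <- tp * x
  J <- stats::mvfft(rbind(xt, matrix(0, nfft - n, k)))
  keep <- freqs >= fmin & freqs <= fmax
  list(J = J[which(keep), , drop = FALSE] / sqrt(rate),
       freqs = freqs[keep])
}

band_aggregate <- function(freqs, values, bands = default_bands()) {
  out <- lapply(bands, function(b) {
    sel <- freqs >= b$lo & freqs <= b$hi
    if (!any(sel)) return(list(mean = NA_real_, peak = NA_real_,
                               peak_freq = NA_real_))
    v <- values[sel]; f <- freqs[sel]
    list(mean = mean(v), peak = max(v), peak_freq = f[which.max(v)])
  })
  names(out) <- names(bands)
  out
}

spectral_metric <- function(freqs, values, kind,
                            bands = default_bands()) {
  structure(list(freqs = freqs, values = values, kind = kind,
                 band_aggregates = band_aggregate(freqs, values, bands)),
            class = "spectral_metric")
}

#' @export
print.spectral_metric <- function(x, ...) {
  cat(sprintf("<spectral_metric> %s: %d freqs %.3g-%.3g Hz\n",
              x$kind, length(x$freqs), min(x$freqs), max(x$freqs)))
  for (b in names(x$band_aggregates)) {
    a <- x$band_aggregates[[b]]
    cat(sprintf("  %-6s mean %8.4g  peak %8.4g @ %.2f Hz\n",
                b, a$mean, a$peak, a$peak_freq))
  }
  invisible(x)
}

#' Multitaper power spectral density
#'
#' Taper-averaged PSD reported as `10*log10` power, restricted to
#' 0.1-48 Hz. A degenerate all-zero record returns the floor value
#' (-300 dB) with a warning instead of -Inf.
#'
#' @param x numeric vector or single-channel `lfp_recording`.
#' @param rate sampling rate (taken from the recording if given).
#' @param plan a `taper_plan`; window defaults to the whole record.
#' @param bands band set for aggregates.
#' @return a `spectral_metric` of kind "power_db".
#' @export
mt_power <- function(x, rate = NULL, plan = plan_session(),
                     bands = default_bands()) {
  if (inherits(x, "lfp_recording")) { rate <- x$rate_hz; x <- x$data[1L, ] }
  if (is.null(rate)) stop("rate required")
  win <- if (is.null(plan$window_s)) length(x) / rate else plan$window_s
  if (length(x) < round(win * rate)) stop("record shorter than the plan window")
  segs <- segment_windows(lfp_recording(x, rate), win_s = win)
  acc <- NULL
  for (s in segs$starts) {
    seg <- x[(s + 1):(s + segs$len)]
    ft <- mt_fft(seg - mean(seg), rate, plan)
    p <- rowMeans(Mod(ft$J)^2)
    acc <- if (is.null(acc)) p else acc + p
    freqs <- ft$freqs
  }
  psd <- acc / length(segs$starts)
  if (all(psd == 0)) {
    warning("all-zero record: power floored at -300 dB")
    vals <- rep(-300, length(psd))
  } else {
    vals <- 10 * log10(pmax(psd, 1e-30))
  }
  spectral_metric(freqs, vals, "power_db", bands)
}

#' Multitaper coherence magnitude and phase
#'
#' Cross- and auto-spectra are averaged over tapers (and windows when the
#' plan is binned) before normalization:
#' magnitude `|Sxy| / sqrt(Sxx*Syy)` and phase `arg(Sxy)` in degrees.
#'
#' @param x,y equal-length numeric vectors (or a 2-channel recording as x).
#' @param rate sampling rate.
#' @param plan a `taper_plan`.
#' @param bands band set for aggregates.
#' @return list with `magnitude` and `phase` `spectral_metric`s.
#' @export
mt_coherence <- function(x, y = NULL, rate = NULL, plan = plan_session(),
                         bands = default_bands()) {
  if (inherits(x, "lfp_recording")) {
    rate <- x$rate_hz
    y <- x$data[2L, ]; x <- x$data[1L, ]
  }
  if (length(x) != length(y)) stop("signals must have equal length")
  if (is.null(rate)) stop("rate required")
  win <- if (is.null(plan$window_s)) length(x) / rate else plan$window_s
  segs <- segment_windows(lfp_recording(x, rate), win_s = win)
  sxx <- syy <- NULL; sxy <- NULL
  for (s in segs$starts) {
    i <- (s + 1):(s + segs$len)
    fx <- mt_fft(x[i] - mean(x[i]), rate, plan)
    fy <- mt_fft(y[i] - mean(y[i]), rate, plan)
    sxx <- if (is.null(sxx)) rowMeans(Mod(fx$J)^2) else sxx + rowMeans(Mod(fx$J)^2)
    syy <- if (is.null(syy)) rowMeans(Mod(fy$J)^2) else syy + rowMeans(Mod(fy$J)^2)
    cs <- rowMeans(fx$J * Conj(fy$J))
    sxy <- if (is.null(sxy)) cs else sxy + cs
    freqs <- fx$freqs
  }
  coh <- Mod(sxy) / sqrt(sxx * syy)
  coh[!is.finite(coh)] <- 0
  coh <- pmin(coh, 1)
  ph <- rad2deg(Arg(sxy))
  list(magnitude = spectral_metric(freqs, coh, "coherence", bands),
       phase = spectral_metric(freqs, ph, "coherence_phase_deg", bands))
}

#' Power/coherence spectra in consecutive time bins
#'
#' One spectrum per non-overlapping bin (default 10 s with the 1 Hz /
#' 19-taper plan), for temporal analysis.
#'
#' @param x,y signals; y NULL gives binned power of x, else binned coherence.
#' @param rate sampling rate.
#' @param bin_s bin length in seconds.
#' @param plan plan applied within each bin.
#' @param bands band set.
#' @return list of `spectral_metric` (power) or of magnitude/phase lists.
#' @export
binned_spectra <- function(x, y = NULL, rate, bin_s = 10,
                           plan = taper_plan(1, 19, window_s = bin_s),
                           bands = default_bands()) {
  nbin <- floor(length(x) / (bin_s * rate))
  if (nbin < 1) stop("record shorter than one bin")
  lapply(seq_len(nbin), function(b) {
    i <- ((b - 1) * bin_s * rate + 1):(b * bin_s * rate)
    if (is.null(y)) mt_power(x[i], rate, plan, bands)
    else mt_coherence(x[i], y[i], rate, plan, bands)
  })
}
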