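# Non-directional phase synchronization from per-segment cross-spectra:
# debiased wPLI, phase-locking value, pairwise phase consistency.

#' Per-segment complex cross-spectra
#'
#' The record pair is cut into non-overlapping windows (default 1 s), each
#' window is mean-removed, Hann-tapered, zero-padded to the next power of
#' two, and the per-window cross-spectrum `Fx * Conj(Fy)` is returned. A
#' multitaper variant (Slepians at `smoothing_hz` half-bandwidth, averaged
#' within window) is available via `taper = "dpss"`.
#'
#' @param x,y equal-length signals (or a 2-channel `lfp_recording` as x).
#' @param rate sampling rate.
#' @param win_s window length in seconds (default 1).
#' @param pad_pow2 zero-pad windows to the next power of two.
#' @param taper "hann" (default) or "dpss".
#' @param smoothing_hz half-bandwidth for the dpss variant.
#' @param fmax keep frequencies up to this limit (Hz).
#' @return a `cross_spectrum_set`: `freqs`, `csd` (segments x freqs complex
#'   matrix), `n_segments`.
#' @export
cross_spectra <- function(x, y = NULL, rate = NULL, win_s = 1,
                          pad_pow2 = TRUE, taper = c("hann", "dpss"),
                          smoothing_hz = 0.5, fmax = 48) {
  taper <- match.arg(taper)
  if (inherits(x, "lfp_recording")) {
    rate <- x$rate_hz
    y <- x$data[2L, ]; x <- x$data[1L, ]
  }
  if (length(x) != length(y)) stop("signals must have equal length")
  segs <- segment_windows(lfp_recording(x, rate), win_s, 0, pad_pow2)
  if (length(segs$starts) < 2) stop("need at least 2 full windows")
  len <- segs$len; nfft <- segs$pad_to
  tp <- switch(taper,
    hann = matrix(0.5 - 0.5 * cos(2 * pi * seq_len(len) / (len + 1)), ncol = 1),
    dpss = {
      nw <- (len / rate) * smoothing_hz
      k <- max(1L, floor(2 * nw - 1))
      dpss_tapers(len, max(nw, 1), k)
    })
  freqs <- (0:(nfft / 2)) * rate / nfft
  keep <- which(freqs > 0 & freqs <= fmax)
  csd <- matrix(0i, length(segs$starts), length(keep))
  for (j in seq_along(segs$starts)) {
    i <- (segs$starts[j] + 1):(segs$starts[j] + len)
    xs <- x[i] - mean(x[i]); ys <- y[i] - mean(y[i])
    Fx <- stats::mvfft(rbind(tp * xs, matrix(0, nfft - len, ncol(tp))))
    Fy <- stats::mvfft(rbind(tp * ys, matrix(0, nfft - len, ncol(tp))))
    cs <- rowMeans(Fx[keep, , drop = FALSE] * Conj(Fy[keep, , drop = FALSE]))
    csd[j, ] <- cs
  }
  structure(list(freqs = freqs[keep], csd = csd,
                 n_segments = length(segs$starts)),
            class = "cross_spectrum_set")
}

#' @export
print.cross_spectrum_set <- function(x, ...) {
  cat(sprintf("<cross_spectrum_set> %d segments x %d freqs (%.3g-%.3g Hz)\n",
              x$n_segments, length(x$freqs), min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Debiased weighted phase-lag index (squared)
#'
#' Per frequency: `(sum_{j<k} Im(Xj) Im(Xk)) / (sum_{j<k} |Im(Xj)||Im(Xk)|)`
#' computed by the sum trick `((S)^2 - S2) / (A^2 - S2)` with
#' `S = sum Im`, `A = sum |Im|`, `S2 = sum Im^2`. 0/0 is defined as 0
#' (zero-lag mixing leaves no imaginary energy). The estimator is unbiased
#' and may be negative; values are reported as-is.
#'
#' @param cs a `cross_spectrum_set` (n_segments >= 2).
#' @param bands band set for aggregates.
#' @return a `spectral_metric` of kind "wpli_debiased".
#' @export
wpli_debiased <- function(cs, bands = default_bands()) {
  if (cs$n_segments < 2) stop("debiased wPLI needs >= 2 segments")
  im <- Im(cs$csd)
  s <- colSums(im)
  s2 <- colSums(im^2)
  a <- colSums(abs(im))
  num <- s^2 - s2
  den <- a^2 - s2
  v <- ifelse(den == 0, 0, num / den)
  spectral_metric(cs$freqs, v, "wpli_debiased", bands)
}

#' Phase-locking value
#'
#' Resultant length of the per-segment cross-spectrum phases:
#' `|mean_j exp(i arg(Xj))|`, in `[0, 1]`.
#'
#' @inheritParams wpli_debiased
#' @return a `spectral_metric` of kind "plv".
#' @export
plv <- function(cs, bands = default_bands()) {
  ph <- cs$csd / Mod(cs$csd)
  ph[!is.finite(ph)] <- 0i
  v <- Mod(colMeans(ph))
  spectral_metric(cs$freqs, pmin(v, 1), "plv", bands)
}

#' Pairwise phase consistency
#'
#' Mean cosine of phase differences over all unordered segment pairs;
#' algebraically `(n * PLV^2 - 1) / (n - 1)`, the sample-size-unbiased
#' counterpart of the PLV.
#'
#' @inheritParams wpli_debiased
#' @return a `spectral_metric` of kind "ppc".
#' @export
ppc <- function(cs, bands = default_bands()) {
  n <- cs$n_segments
  if (n < 2) stop("PPC needs >= 2 segments")
  v <- (n * plv(cs, bands)$values^2 - 1) / (n - 1)
  spectral_metric(cs$freqs, v, "ppc", bands)
}
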