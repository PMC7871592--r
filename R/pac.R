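# Cross-regional theta-gamma phase-amplitude coupling:
# Kullback-Leibler modulation index over 18 x 20-degree phase bins.

#' Phase-amplitude modulation index
#'
#' Theta phases are binned into eighteen 20-degree intervals (bin 1 spans
#' [-180, -160) degrees in the wrapped convention); the mean gamma
#' amplitude per bin is normalized to a probability profile P and
#' `MI = KL(P || uniform) / log(18) = (log 18 - H(P)) / log 18`, in
#' `[0, 1]`. The record is split into bins of `bin_minutes` (default 1)
#' and the per-bin MI values are averaged; an empty phase bin contributes
#' `0 * log 0 := 0`.
#'
#' @param theta_phase `analytic_signal` (phase used) from the theta band of
#'   region A, or a radian phase vector.
#' @param gamma_amp `analytic_signal` (amplitude used) from the gamma band
#'   of region B, or a non-negative amplitude vector.
#' @param rate_hz required when passing plain vectors.
#' @param bin_minutes temporal bin length in minutes; NULL = single bin.
#' @param n_bins number of phase bins (18).
#' @param direction label naming the theta region first.
#' @return a `pac_result`: `mi` (mean over time bins), `mi_bins`
#'   (per-bin values), `profile` (overall 18-bin mean-amplitude profile),
#'   `direction`.
#' @export
modulation_index <- function(theta_phase, gamma_amp, rate_hz = NULL,
                             bin_minutes = 1, n_bins = 18L,
                             direction = "thetaRegion->gammaRegion") {
  if (inherits(theta_phase, "analytic_signal")) {
    rate_hz <- theta_phase$rate_hz
    theta_phase <- theta_phase$phase
  }
  if (inherits(gamma_amp, "analytic_signal")) {
    rate_hz <- gamma_amp$rate_hz
    gamma_amp <- gamma_amp$amplitude
  }
  if (length(theta_phase) != length(gamma_amp))
    stop("phase and amplitude series must have equal length")
  if (all(gamma_amp == 0)) stop("all-zero amplitude signal")
  n <- length(theta_phase)
  if (is.null(bin_minutes) || is.null(rate_hz)) {
    idx <- list(seq_len(n))
  } else {
    bl <- round(bin_minutes * 60 * rate_hz)
    nb <- max(1L, floor(n / bl))
    idx <- lapply(seq_len(nb), function(b)
      if (b < nb) ((b - 1) * bl + 1):(b * bl) else ((nb - 1) * bl + 1):n)
  }
  mi_bins <- vapply(idx, function(i)
    mi_one(theta_phase[i], gamma_amp[i], n_bins)$mi, numeric(1))
  prof <- mi_one(theta_phase, gamma_amp, n_bins)$profile
  structure(list(mi = mean(mi_bins), mi_bins = mi_bins, profile = prof,
                 n_bins = n_bins, direction = direction),
            class = "pac_result")
}

mi_one <- function(phase, amp, n_bins) {
  # bin 1 = [-pi, -pi + 2pi/n_bins)
  b <- floor((wrap_pi(phase) + pi) / (2 * pi / n_bins)) + 1L
  b[b > n_bins] <- n_bins  # phase == pi lands in the last bin
  prof <- vapply(seq_len(n_bins), function(k) {
    sel <- b == k
    if (any(sel)) mean(amp[sel]) else 0
  }, numeric(1))
  tot <- sum(prof)
  if (tot == 0) return(list(mi = 0, profile = prof))
  p <- prof / tot
  h <- -sum(ifelse(p > 0, p * log(p), 0))
  list(mi = (log(n_bins) - h) / log(n_bins), profile = prof)
}

#' @export
print.pac_result <- function(x, ...) {
  cat(sprintf("<pac_result> MI = %.4f (%s; %d time bins)\n",
              x$mi, x$direction, length(x$mi_bins)))
  invisible(x)
}
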