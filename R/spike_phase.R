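# Multi-unit spike extraction and spike-phase coupling against
# trough-interpolated theta phase: MRL, mean angle, offset profile.

#' Multi-unit activity extraction
#'
#' High-pass filters the wideband trace above 800 Hz and detects threshold
#' crossings at `mean + 3.5 SD` of the filtered signal. Events staying
#' above threshold for more than 2 ms are rejected as artifacts; of any
#' pair of spikes closer than 1 ms, the second is dropped. Spike time is
#' the first supra-threshold sample.
#'
#' @param raw numeric vector (wideband, >= 10 kHz recommended) or a
#'   single-channel `lfp_recording`.
#' @param rate_hz sampling rate for plain vectors.
#' @param hp_hz high-pass edge (default 800).
#' @param thresh_sd threshold in SDs above the mean (default 3.5).
#' @param max_width_ms supra-threshold duration cutoff (default 2).
#' @param refractory_ms minimum inter-spike interval (default 1).
#' @return a `spike_train` (possibly empty for flat input).
#' @export
extract_mua <- function(raw, rate_hz = NULL, hp_hz = 800, thresh_sd = 3.5,
                        max_width_ms = 2, refractory_ms = 1) {
  if (inherits(raw, "lfp_recording")) { rate_hz <- raw$rate_hz; raw <- raw$data[1L, ] }
  if (stats::sd(raw) == 0)
    return(structure(list(times = numeric(0), n = 0L, source = "mua"),
                     class = "spike_train"))
  hf <- fir_highpass(raw, hp_hz, rate_hz)
  thr <- mean(hf) + thresh_sd * stats::sd(hf)
  times <- threshold_spike_times(hf, thr, rate_hz, max_width_ms,
                                 refractory_ms)
  structure(list(times = times, n = length(times), source = "mua"),
            class = "spike_train")
}

# spike times from threshold crossings of a (filtered) trace:
# time = first supra-threshold sample; events staying above threshold
# longer than max_width_ms are artifacts; of any pair closer than
# refractory_ms the second is dropped
threshold_spike_times <- function(x, thr, rate_hz, max_width_ms = 2,
                                  refractory_ms = 1) {
  above <- x > thr
  if (!any(above)) return(numeric(0))
  d <- diff(c(FALSE, above))
  starts <- which(d == 1L)
  ends <- which(d == -1L) - 1L
  if (length(ends) < length(starts)) ends <- c(ends, length(above))
  width_ms <- (ends - starts + 1) / rate_hz * 1000
  starts <- starts[width_ms <= max_width_ms]
  times <- (starts - 1) / rate_hz
  if (length(times) > 1) {
    keep <- logical(length(times)); keep[1] <- TRUE
    last <- times[1]
    for (i in 2:length(times)) {
      if (times[i] - last >= refractory_ms / 1000) {
        keep[i] <- TRUE; last <- times[i]
      }
    }
    times <- times[keep]
  }
  times
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes", x$n))
  if (x$n > 0) cat(sprintf(" over %.1f s", max(x$times) - min(x$times)))
  cat("\n"); invisible(x)
}

#' Trough-interpolated theta phase
#'
#' Band-passes the LFP to 5-12 Hz, locates oscillation troughs, and ramps
#' the phase linearly 0 -> 360 degrees between consecutive troughs
#' (trough = 0/360, peak ~ 180 for symmetric cycles). This tracks
#' asymmetric (speed-dependent) theta waveforms that bias the Hilbert
#' phase. A validity mask gates samples where the Hilbert theta envelope
#' exceeds its mean plus `gate_sd` SDs (set `gate_mode = "sd_only"` for
#' the alternative reading amplitude > `gate_sd` * SD).
#'
#' @param lfp numeric vector or single-channel `lfp_recording`.
#' @param rate_hz rate for plain vectors.
#' @param band theta band (default 5-12 Hz).
#' @param gate_sd gate level in SD units (default 0.25).
#' @param gate_mode "mean_plus_sd" (default) or "sd_only".
#' @return a `theta_phase_series`: `phase_deg` in `[0, 360)` per sample,
#'   `valid`, `rate_hz`, `troughs` (sample indices), `gate` metadata.
#' @export
theta_phase_interp <- function(lfp, rate_hz = NULL,
                               band = band_spec("theta", 5, 12),
                               gate_sd = 0.25,
                               gate_mode = c("mean_plus_sd", "sd_only")) {
  gate_mode <- match.arg(gate_mode)
  if (inherits(lfp, "lfp_recording")) { rate_hz <- lfp$rate_hz; lfp <- lfp$data[1L, ] }
  xf <- fir_bandpass(lfp, band$lo, band$hi, rate_hz)
  # troughs: local minima of the band-passed trace, refined to sub-sample
  # position by a parabola through the three samples around the minimum
  # (the half-sample quantization otherwise biases the phase by ~1 degree)
  d <- diff(xf)
  tr <- which(d[-length(d)] < 0 & d[-1] >= 0) + 1L
  tr <- tr[tr > 1L & tr < length(xf)]
  if (length(tr) < 2) stop("no theta troughs found")
  curv <- xf[tr - 1L] - 2 * xf[tr] + xf[tr + 1L]
  shift <- ifelse(curv > 0, 0.5 * (xf[tr - 1L] - xf[tr + 1L]) / curv, 0)
  tr_frac <- tr + pmax(pmin(shift, 0.5), -0.5)
  n <- length(xf)
  phase <- rep(NA_real_, n)
  for (k in seq_len(length(tr) - 1L)) {
    t0 <- tr_frac[k]; t1 <- tr_frac[k + 1L]
    idx <- ceiling(t0):floor(t1 - 1e-9)
    phase[idx] <- 360 * (idx - t0) / (t1 - t0)
  }
  amp <- Mod(analytic_fft(xf))
  lvl <- switch(gate_mode,
                mean_plus_sd = mean(amp) + gate_sd * stats::sd(amp),
                sd_only = gate_sd * stats::sd(amp))
  valid <- !is.na(phase) & amp > lvl
  structure(list(phase_deg = phase, valid = valid, rate_hz = rate_hz,
                 troughs = tr,
                 gate = list(mode = gate_mode, sd = gate_sd, level = lvl)),
            class = "theta_phase_series")
}

#' @export
print.theta_phase_series <- function(x, ...) {
  cat(sprintf("<theta_phase_series> %d samples @ %g Hz, %d troughs, %.1f%% valid (gate: %s %.2f)\n",
              length(x$phase_deg), x$rate_hz, length(x$troughs),
              100 * mean(x$valid), x$gate$mode, x$gate$sd))
  invisible(x)
}

#' Spike-phase coupling (MRL and mean angle)
#'
#' Assigns each spike inside the validity mask its interpolated theta
#' phase, subsamples exactly `n_fix` spikes uniformly at random (seeded) to
#' equalize spike counts across recordings, and returns the mean resultant
#' length and angle. Recordings with fewer than `n_fix` eligible spikes
#' are reported as excluded rather than estimated.
#'
#' @param spikes a `spike_train`.
#' @param phase a `theta_phase_series`.
#' @param n_fix fixed spike count (default 1000).
#' @param seed subsampling seed.
#' @param offset_ms shift applied to spike times before phase lookup (ms).
#' @return a `spike_phase_result`: `mrl`, `mean_angle_deg`,
#'   `n_spikes_used`, `status` ("ok" or "excluded"), `phases_deg`.
#' @export
spike_phase_coupling <- function(spikes, phase, n_fix = 1000L, seed = 1L,
                                 offset_ms = 0) {
  idx <- round((spikes$times + offset_ms / 1000) * phase$rate_hz) + 1L
  ok <- idx >= 1L & idx <= length(phase$phase_deg)
  idx <- idx[ok]
  idx <- idx[phase$valid[idx]]
  if (length(idx) < n_fix)
    return(structure(list(mrl = NA_real_, mean_angle_deg = NA_real_,
                          n_spikes_used = length(idx), status = "excluded",
                          phases_deg = numeric(0)),
                     class = "spike_phase_result"))
  set.seed(seed)
  use <- sample(idx, n_fix)
  ph <- deg2rad(phase$phase_deg[use])
  rv <- circ_resultant(ph)
  structure(list(mrl = rv$r, mean_angle_deg = rad2deg(rv$mu) %% 360,
                 n_spikes_used = n_fix, status = "ok",
                 phases_deg = phase$phase_deg[use]),
            class = "spike_phase_result")
}

#' @export
print.spike_phase_result <- function(x, ...) {
  if (x$status == "excluded")
    cat(sprintf("<spike_phase_result> EXCLUDED (%d eligible spikes)\n",
                x$n_spikes_used))
  else
    cat(sprintf("<spike_phase_result> MRL %.3f @ %.1f deg (n = %d)\n",
                x$mrl, x$mean_angle_deg, x$n_spikes_used))
  invisible(x)
}

#' Phase-locking across temporal offsets
#'
#' Recomputes the MRL with spike times shifted by each offset on the
#' -100..+100 ms grid in 4-ms steps (51 points). A peak at a positive
#' offset means spikes lock best to the upcoming theta cycle (spiking
#' leads theta). The same subsample seed is used at every offset.
#'
#' @param spikes,phase,n_fix,seed as in [spike_phase_coupling()].
#' @param offsets_ms offset grid (ms).
#' @return list: `offsets_ms`, `mrl` profile, `best_offset_ms`, `status`.
#' @export
shifted_mrl <- function(spikes, phase, n_fix = 1000L, seed = 1L,
                        offsets_ms = seq(-100, 100, by = 4)) {
  prof <- vapply(offsets_ms, function(o) {
    r <- spike_phase_coupling(spikes, phase, n_fix, seed, offset_ms = o)
    if (r$status == "ok") r$mrl else NA_real_
  }, numeric(1))
  if (all(is.na(prof)))
    return(list(offsets_ms = offsets_ms, mrl = prof,
                best_offset_ms = NA_real_, status = "excluded"))
  list(offsets_ms = offsets_ms, mrl = prof,
       best_offset_ms = offsets_ms[which.max(prof)], status = "ok")
}

#' Watson-Williams comparison of group phase angles
#'
#' @param angles_a,angles_b per-recording mean angles in degrees.
#' @return list with `F`, `p` (see [watson_williams()]).
#' @export
phase_angle_compare <- function(angles_a, angles_b) {
  watson_williams(deg2rad(angles_a), deg2rad(angles_b))
}
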