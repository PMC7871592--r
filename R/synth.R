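# Synthetic LFP / spike generation with known coupling ground truth.
# Every generator is deterministic given its seed; a scenario-level seed
# spawns per-block substreams so blocks stay independent yet reproducible.

#' Deterministic substream seed
#'
#' Derives a child seed from a top-level seed and a block index so that
#' independent generator blocks use independent, reproducible streams.
#' @param seed top-level integer seed.
#' @param k block index (>= 1).
#' @return an integer seed below 2^31.
#' @export
substream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 16807) %% 2147483647)
}

#' Spectral radius of a VAR companion matrix
#' @param A list of p coefficient matrices (n x n).
#' @return largest eigenvalue modulus; < 1 means the VAR is stable.
#' @export
var_companion_radius <- function(A) {
  p <- length(A); n <- nrow(A[[1L]])
  C <- matrix(0, n * p, n * p)
  for (k in seq_len(p)) C[1:n, ((k - 1) * n + 1):(k * n)] <- A[[k]]
  if (p > 1) C[(n + 1):(n * p), 1:(n * (p - 1))] <- diag(n * (p - 1))
  max(Mod(eigen(C, only.values = TRUE)$values))
}

#' Simulate a stable VAR process as an LFP recording
#'
#' Drives the vector-autoregressive recursion
#' `x_t = A_1 x_{t-1} + ... + A_p x_{t-p} + e_t`, `e_t ~ N(0, Sigma)`,
#' and discards a burn-in of `10 * p` samples so the output is stationary.
#' This is the ground-truth bench for Granger-causality estimation: the
#' true directed influence is fixed by `(A, Sigma)`.
#'
#' @param A list of p coefficient matrices (n x n); must be stable.
#' @param Sigma innovation covariance (n x n, symmetric positive definite).
#' @param duration_s output duration in seconds.
#' @param rate_hz sampling rate.
#' @param labels channel labels.
#' @param seed integer seed.
#' @return an `lfp_recording` with n channels.
#' @export
gen_var_lfp <- function(A, Sigma, duration_s, rate_hz,
                        labels = NULL, seed = 1L) {
  if (is.matrix(A)) A <- list(A)
  p <- length(A); n <- nrow(A[[1L]])
  rho <- var_companion_radius(A)
  if (rho >= 1)
    stop(sprintf("unstable VAR: companion spectral radius %.4f >= 1", rho))
  ev <- eigen(Sigma, symmetric = TRUE)
  if (any(ev$values <= 0)) stop("Sigma must be positive definite")
  L <- ev$vectors %*% diag(sqrt(ev$values), n) %*% t(ev$vectors)
  nt <- round(duration_s * rate_hz)
  burn <- 10L * p
  total <- nt + burn
  set.seed(seed)
  E <- L %*% matrix(stats::rnorm(n * total), n, total)
  X <- matrix(0, n, total)
  X[, 1:p] <- E[, 1:p]
  for (t in (p + 1):total) {
    acc <- E[, t]
    for (k in seq_len(p)) acc <- acc + A[[k]] %*% X[, t - k]
    X[, t] <- acc
  }
  lfp_recording(X[, (burn + 1):total, drop = FALSE], rate_hz, labels)
}

#' Phase-lagged oscillator pair
#'
#' Two channels sharing a sinusoid at `f` Hz, the second delayed by a fixed
#' phase lag, with independent Gaussian noise per channel. SNR is the ratio
#' of sinusoid variance (0.5) to noise variance.
#'
#' @param f oscillation frequency in Hz (< Nyquist).
#' @param lag_deg phase of channel 2 relative to channel 1, degrees
#'   (positive: channel 2 lags).
#' @param snr signal-to-noise variance ratio; `Inf` for noise-free.
#' @param duration_s,rate_hz,labels,seed as in [gen_var_lfp()].
#' @return a 2-channel `lfp_recording`.
#' @export
gen_phase_lagged_pair <- function(f, lag_deg, snr, duration_s, rate_hz,
                                  labels = c("A", "B"), seed = 1L) {
  if (f <= 0 || f >= rate_hz / 2) stop("f must lie in (0, Nyquist)")
  nt <- round(duration_s * rate_hz)
  t <- (seq_len(nt) - 1) / rate_hz
  x1 <- cos(2 * pi * f * t)
  x2 <- cos(2 * pi * f * t - deg2rad(lag_deg))
  set.seed(seed)
  if (is.finite(snr)) {
    sd_n <- sqrt(0.5 / snr)
    x1 <- x1 + stats::rnorm(nt, sd = sd_n)
    x2 <- x2 + stats::rnorm(nt, sd = sd_n)
  }
  lfp_recording(rbind(x1, x2), rate_hz, labels)
}

#' Zero-lag common-source (volume-conduction) mixing
#'
#' Each output channel is an instantaneous weighted copy of the source(s)
#' plus independent sensor noise — the textbook volume-conduction confound:
#' the cross-spectrum is purely real, so lag-based measures stay at zero
#' while coherence saturates.
#'
#' @param mixing numeric matrix, channels x sources.
#' @param source numeric vector (one source) or sources x samples matrix;
#'   if NULL, band-limited Gaussian sources (2-20 Hz) are generated.
#' @param duration_s,rate_hz used when generating the source.
#' @param noise_sd per-channel independent noise SD.
#' @param labels,seed as elsewhere.
#' @return an `lfp_recording` with `nrow(mixing)` channels.
#' @export
gen_common_source <- function(mixing, source = NULL, duration_s = 60,
                              rate_hz = 1000, noise_sd = 0,
                              labels = NULL, seed = 1L) {
  if (is.vector(mixing)) mixing <- matrix(mixing, ncol = 1L)
  set.seed(seed)
  if (is.null(source)) {
    nt <- round(duration_s * rate_hz)
    source <- t(vapply(seq_len(ncol(mixing)), function(i)
      fir_bandpass(stats::rnorm(nt), 2, 20, rate_hz), numeric(nt)))
    source <- source / apply(source, 1L, stats::sd)
  }
  if (is.vector(source)) source <- matrix(source, nrow = 1L)
  if (ncol(mixing) != nrow(source)) stop("mixing columns must match sources")
  if (any(!is.finite(mixing))) stop("mixing matrix has non-finite entries")
  out <- mixing %*% source
  if (noise_sd > 0)
    out <- out + matrix(stats::rnorm(length(out), sd = noise_sd),
                        nrow(out), ncol(out))
  lfp_recording(out, rate_hz, labels)
}

#' Cross-regional phase-amplitude-coupled pair
#'
#' Channel A carries a theta sinusoid; channel B carries a gamma carrier
#' whose envelope is `1 + m * cos(theta_phase - phi0)`, plus optional
#' broadband noise. `m` is the ground-truth modulation depth.
#'
#' @param f_theta theta frequency (Hz).
#' @param f_gamma gamma carrier frequency (> 2 * f_theta).
#' @param m modulation depth in `[0, 1]`.
#' @param duration_s,rate_hz,seed as elsewhere.
#' @param phi0 preferred theta phase of the gamma envelope, radians.
#' @param noise_sd broadband noise SD added to both channels.
#' @return a 2-channel `lfp_recording` labelled theta-region / gamma-region.
#' @export
gen_pac_signal <- function(f_theta, f_gamma, m, duration_s, rate_hz,
                           phi0 = 0, noise_sd = 0, seed = 1L) {
  if (m < 0 || m > 1) stop("modulation depth m must be in [0, 1]")
  if (f_gamma <= 2 * f_theta) stop("need f_gamma > 2 * f_theta")
  if (f_gamma >= rate_hz / 2) stop("gamma carrier at or above Nyquist")
  nt <- round(duration_s * rate_hz)
  t <- (seq_len(nt) - 1) / rate_hz
  th_phase <- 2 * pi * f_theta * t
  a <- cos(th_phase)
  env <- 1 + m * cos(th_phase - phi0)
  b <- env * cos(2 * pi * f_gamma * t)
  set.seed(seed)
  if (noise_sd > 0) {
    a <- a + stats::rnorm(nt, sd = noise_sd)
    b <- b + stats::rnorm(nt, sd = noise_sd)
  }
  lfp_recording(rbind(a, b), rate_hz, c("thetaRegion", "gammaRegion"))
}

#' Spikes von-Mises-locked to an oscillation's phase
#'
#' Draws target phases from von Mises(mu, kappa), places each spike at a
#' uniformly chosen cycle of the phase series at that phase (by inverting
#' the unwrapped phase), then applies a uniform delay and rounds to the
#' sampling grid.
#'
#' @param phase instantaneous phase in radians per sample (monotone modulo
#'   2*pi), or an `analytic_signal`.
#' @param rate_hz sampling rate of the phase series.
#' @param mu_deg preferred phase, degrees.
#' @param kappa von Mises concentration (>= 0).
#' @param n_spikes number of spikes.
#' @param delay_ms uniform delay applied to all spike times (ms).
#' @param seed integer seed.
#' @return a `spike_train`: list with sorted `times` (s) and `n`.
#' @export
gen_locked_spikes <- function(phase, rate_hz, mu_deg, kappa, n_spikes,
                              delay_ms = 0, seed = 1L) {
  if (inherits(phase, "analytic_signal")) {
    rate_hz <- phase$rate_hz
    phase <- phase$phase
  }
  if (n_spikes < 1) stop("need n_spikes >= 1")
  if (kappa < 0) stop("kappa must be >= 0")
  # tolerate undefined phase at the record edges (before the first / after
  # the last oscillation trough)
  ok <- which(!is.na(phase))
  if (length(ok) < 2) stop("phase source too short: no defined phase")
  phase <- phase[ok[1]:ok[length(ok)]]
  if (anyNA(phase)) stop("phase series has interior gaps")
  t <- (ok[1] - 1 + seq_along(phase) - 1) / rate_hz
  un <- unwrap_phase(phase)
  n_cycles <- floor((un[length(un)] - un[1]) / (2 * pi)) - 1L
  if (n_cycles < 1) stop("phase source too short: fewer than one full cycle")
  set.seed(seed)
  target <- rvonmises(n_spikes, deg2rad(mu_deg), kappa)
  cyc <- sample.int(n_cycles, n_spikes, replace = TRUE)
  base <- 2 * pi * ceiling(un[1] / (2 * pi))
  utarget <- base + (cyc - 1) * 2 * pi + (target %% (2 * pi))
  times <- stats::approx(un, t, xout = utarget, rule = 2)$y
  times <- times + delay_ms / 1000
  times <- round(times * rate_hz) / rate_hz  # detection-grid resolution
  times <- sort(times)
  structure(list(times = times, n = length(times), source = "synthetic"),
            class = "spike_train")
}

# cumulative unwrapping of a wrapped phase series (monotone output)
unwrap_phase <- function(phi) {
  d <- diff(phi)
  d <- ifelse(d < -pi, d + 2 * pi, ifelse(d > pi, d - 2 * pi, d))
  u <- cumsum(c(phi[1], pmax(d, 0)))
  u
}

#' Two-group cohort with within-session coupling drift
#'
#' Simulates per-subject 2-channel recordings in which channel B receives a
#' delayed copy of channel A's narrowband (theta) component with coupling
#' weight drifting linearly over the session: `w(t) = w0 + slope * t_min`.
#' Group means, per-subject jitter and group-specific slopes are the
#' planted ground truth for group-comparison and slope-recovery analyses.
#'
#' @param group_specs named list of groups, each a list with `n_subjects`,
#'   `coupling` (mean starting weight w0), `slope` (weight change per
#'   minute), `jitter_sd` (between-subject SD of w0), and optionally
#'   `lag_ms` (transmission delay, default 20).
#' @param duration_s,rate_hz session geometry.
#' @param f_band narrowband carrier range (Hz), default theta 5-12.
#' @param noise_sd independent broadband noise per channel.
#' @param common_pickup weight of a shared broadband source added to both
#'   region channels (volume-conducted reference pickup); the source is
#'   also emitted as a third "REF" channel so analyses can re-reference
#'   against it.
#' @param seed top-level seed; subjects use substreams.
#' @return list with `recordings` (list of 3-channel `lfp_recording`:
#'   A, B, REF) and `meta` (data.frame: subject, group, seed, w0, slope).
#' @export
gen_cohort <- function(group_specs, duration_s = 120, rate_hz = 250,
                       f_band = c(5, 12), noise_sd = 0.5,
                       common_pickup = 0.3, seed = 1L) {
  for (g in group_specs)
    if (g$n_subjects < 2) stop("need >= 2 subjects per group")
  recs <- list(); meta <- NULL
  idx <- 0L
  for (gname in names(group_specs)) {
    g <- group_specs[[gname]]
    lag_ms <- if (is.null(g$lag_ms)) 20 else g$lag_ms
    for (s in seq_len(g$n_subjects)) {
      idx <- idx + 1L
      sseed <- substream_seed(seed, idx)
      set.seed(sseed)
      nt <- round(duration_s * rate_hz)
      w0 <- g$coupling + stats::rnorm(1, sd = g$jitter_sd)
      carrier <- fir_bandpass(stats::rnorm(nt + rate_hz), f_band[1],
                              f_band[2], rate_hz)
      carrier <- carrier / stats::sd(carrier)
      lag_n <- round(lag_ms / 1000 * rate_hz)
      delayed <- carrier[seq_len(nt)]
      carrier <- carrier[lag_n + seq_len(nt)]
      t_min <- (seq_len(nt) - 1) / rate_hz / 60
      w <- pmax(w0 + g$slope * t_min, 0)
      ref_src <- fir_bandpass(stats::rnorm(nt), 2, 30, rate_hz)
      ref_src <- ref_src / stats::sd(ref_src)
      a <- carrier + common_pickup * ref_src + stats::rnorm(nt, sd = noise_sd)
      b <- w * delayed + common_pickup * ref_src +
        stats::rnorm(nt, sd = noise_sd)
      ref <- ref_src + stats::rnorm(nt, sd = 0.1 * noise_sd)
      recs[[idx]] <- lfp_recording(rbind(a, b, ref), rate_hz,
                                   c("A", "B", "REF"))
      meta <- rbind(meta, data.frame(
        subject = sprintf("s%02d", idx), group = gname, seed = sseed,
        w0 = w0, slope = g$slope))
    }
  }
  list(recordings = recs, meta = meta)
}

#' Synthetic metric table with a planted latent driver
#'
#' Builds a per-subject, per-connection metric table in which two metrics
#' load on a shared latent driver (hence are genuinely redundant) while the
#' remaining metrics are independent noise. Used to validate the redundancy
#' consensus analysis.
#'
#' @param n_subjects subjects per connection.
#' @param connections connection labels (default the three usual pairs).
#' @param shared character vector of the two redundant metric names.
#' @param independent names of independent metrics.
#' @param loading latent-driver loading of the shared metrics.
#' @param seed integer seed.
#' @return data.frame: connection, subject, one column per metric.
#' @export
gen_metric_table <- function(n_subjects = 27,
                             connections = c("PFC-dHC", "PFC-vHC", "vHC-dHC"),
                             shared = c("mA", "mB"),
                             independent = "mC",
                             loading = 0.9, seed = 1L) {
  set.seed(seed)
  out <- NULL
  for (conn in connections) {
    z <- stats::rnorm(n_subjects)
    df <- data.frame(connection = conn,
                     subject = sprintf("s%02d", seq_len(n_subjects)))
    for (m in shared)
      df[[m]] <- loading * z + sqrt(1 - loading^2) * stats::rnorm(n_subjects)
    for (m in independent) df[[m]] <- stats::rnorm(n_subjects)
    out <- rbind(out, df)
  }
  out
}
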