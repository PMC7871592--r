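#' Multi-channel LFP recording
#'
#' Container for uniformly sampled extracellular voltage traces with
#' per-channel region labels and a declared recording reference.
#'
#' @param data numeric matrix, channels x samples (microvolts).
#' @param rate_hz sampling rate in samples/s.
#' @param labels character vector of unique per-channel region labels.
#' @param reference label of the subtracted reference ("ground" by default).
#' @return An object of class `lfp_recording`.
#' @export
lfp_recording <- function(data, rate_hz, labels = NULL, reference = "ground") {
  if (is.vector(data)) data <- matrix(data, nrow = 1L)
  stopifnot(is.matrix(data), is.numeric(data))
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0)
    stop("rate_hz must be a single positive number")
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  if (length(labels) != nrow(data)) stop("one label per channel required")
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  structure(
    list(data = data, rate_hz = rate_hz, labels = as.character(labels),
         reference = reference),
    class = "lfp_recording")
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$rate_hz,
              ncol(x$data) / x$rate_hz))
  cat("  channels:", paste(x$labels, collapse = ", "), "\n")
  cat("  reference:", x$reference, "\n")
  invisible(x)
}

#' @export
`[.lfp_recording` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$labels)
  lfp_recording(x$data[i, , drop = FALSE], x$rate_hz, x$labels[i],
                x$reference)
}

#' Number of samples / duration helpers
#' @param rec an `lfp_recording`.
#' @return integer sample count, or duration in seconds.
#' @export
n_samples <- function(rec) ncol(rec$data)

#' @rdname n_samples
#' @export
duration_s <- function(rec) ncol(rec$data) / rec$rate_hz

#' Extract one channel as a plain numeric vector
#' @param rec an `lfp_recording`.
#' @param channel label or index.
#' @return numeric vector of samples.
#' @export
channel <- function(rec, channel) {
  i <- if (is.character(channel)) match(channel, rec$labels) else channel
  if (is.na(i) || i < 1L || i > nrow(rec$data)) stop("unknown channel: ", channel)
  rec$data[i, ]
}

#' Frequency band specification
#'
#' @param name band name.
#' @param lo,hi band edges in Hz, 0 < lo < hi.
#' @return A `band_spec` object.
#' @export
band_spec <- function(name, lo, hi) {
  if (!(lo > 0 && hi > lo)) stop("need 0 < lo < hi")
  structure(list(name = name, lo = lo, hi = hi), class = "band_spec")
}

#' Canonical frequency bands
#'
#' delta 1-4 Hz, theta 5-12 Hz, beta 15-30 Hz, low gamma 30-48 Hz.
#' @return named list of `band_spec`.
#' @export
default_bands <- function() {
  list(delta = band_spec("delta", 1, 4),
       theta = band_spec("theta", 5, 12),
       beta  = band_spec("beta", 15, 30),
       gamma = band_spec("gamma", 30, 48))
}

#' Analytic (band-limited) signal
#'
#' Instantaneous envelope and phase of a band-passed trace.
#' @param amplitude non-negative envelope (same units as input).
#' @param phase instantaneous phase in radians, wrapped to (-pi, pi].
#' @param band the `band_spec` used.
#' @param rate_hz sampling rate.
#' @return An `analytic_signal` object.
#' @export
analytic_signal <- function(amplitude, phase, band, rate_hz) {
  stopifnot(length(amplitude) == length(phase), all(amplitude >= 0))
  structure(list(amplitude = amplitude, phase = phase, band = band,
                 rate_hz = rate_hz),
            class = "analytic_signal")
}

#' @export
print.analytic_signal <- function(x, ...) {
  cat(sprintf("<analytic_signal> band %s (%g-%g Hz), %d samples @ %g Hz\n",
              x$band$name, x$band$lo, x$band$hi, length(x$amplitude),
              x$rate_hz))
  invisible(x)
}
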