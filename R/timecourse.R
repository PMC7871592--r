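# Per-bin metric time courses and the slope-of-linear-fit summary that
# condenses a metric's within-session change into one number.

#' Slope of a per-bin metric series
#'
#' Ordinary least-squares line over (bin midpoint in minutes, value);
#' the slope is therefore in metric units per minute, comparable across
#' metrics with different bin sizes.
#'
#' @param values per-bin metric values.
#' @param bin_s bin length in seconds (default 60).
#' @param t_min optional explicit abscissa (minutes); overrides bin_s.
#' @return list with `slope` (per minute) and `intercept`.
#' @export
slope_fit <- function(values, bin_s = 60, t_min = NULL) {
  ok <- is.finite(values)
  if (sum(ok) < 2) stop("need at least 2 finite bins")
  if (is.null(t_min))
    t_min <- (seq_along(values) - 0.5) * bin_s / 60
  x <- t_min[ok]; y <- values[ok]
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  list(slope = b, intercept = mean(y) - b * mean(x))
}

#' Metric time course with slope summary
#'
#' Evaluates a metric independently in consecutive bins of its own
#' conventional size (10 s for power/coherence, 1 min for wPLI/PLV/PPC/
#' PAC/GC) and attaches the least-squares slope.
#'
#' @param rec a 2-channel `lfp_recording` (theta-phase channel first for
#'   "pac").
#' @param metric one of "coherence", "power", "wpli", "plv", "ppc", "pac",
#'   "gc".
#' @param band a `band_spec`; band aggregate used per bin (mean; GC band
#'   integral).
#' @param bin_s bin size override (default: the metric's convention).
#' @param ... metric-specific arguments (`plan` for spectral, `order` and
#'   `section_s` for gc, `f_gamma_band` for pac).
#' @return a `metric_timecourse`: `bin_starts_s`, `values`, `slope`,
#'   `intercept`, `metric`, `band`.
#' @export
metric_timecourse <- function(rec, metric, band, bin_s = NULL, ...) {
  args <- list(...)
  default_bin <- switch(metric,
                        coherence = 10, power = 10,
                        wpli = 60, plv = 60, ppc = 60, pac = 60, gc = 60,
                        stop("unknown metric: ", metric))
  if (is.null(bin_s)) bin_s <- default_bin
  rate <- rec$rate_hz
  bl <- round(bin_s * rate)
  nb <- floor(n_samples(rec) / bl)
  if (nb < 2) stop("record covers fewer than 2 bins")
  vals <- vapply(seq_len(nb), function(b) {
    i <- ((b - 1) * bl + 1):(b * bl)
    sub <- lfp_recording(rec$data[, i, drop = FALSE], rate, rec$labels,
                         rec$reference)
    metric_bin_value(sub, metric, band, args)
  }, numeric(1))
  sl <- slope_fit(vals, bin_s)
  structure(list(bin_starts_s = (seq_len(nb) - 1) * bin_s, values = vals,
                 slope = sl$slope, intercept = sl$intercept,
                 metric = metric, band = band$name, bin_s = bin_s),
            class = "metric_timecourse")
}

metric_bin_value <- function(sub, metric, band, args) {
  rate <- sub$rate_hz
  switch(metric,
    power = {
      plan <- args$plan %||% taper_plan(1, 19)
      m <- mt_power(sub$data[1L, ], rate, plan)
      m$band_aggregates[[band$name]]$mean
    },
    coherence = {
      plan <- args$plan %||% taper_plan(1, 19)
      m <- mt_coherence(sub$data[1L, ], sub$data[2L, ], rate, plan)
      m$magnitude$band_aggregates[[band$name]]$mean
    },
    wpli = {
      cs <- cross_spectra(sub$data[1L, ], sub$data[2L, ], rate)
      wpli_debiased(cs)$band_aggregates[[band$name]]$mean
    },
    plv = {
      cs <- cross_spectra(sub$data[1L, ], sub$data[2L, ], rate)
      plv(cs)$band_aggregates[[band$name]]$mean
    },
    ppc = {
      cs <- cross_spectra(sub$data[1L, ], sub$data[2L, ], rate)
      ppc(cs)$band_aggregates[[band$name]]$mean
    },
    pac = {
      gband <- args$f_gamma_band %||% band_spec("gamma", 30, 48)
      th <- bandpass_analytic(sub, band, 1L)
      ga <- bandpass_analytic(sub, gband, 2L)
      modulation_index(th, ga, bin_minutes = NULL)$mi
    },
    gc = {
      p <- args$order %||% 8L
      sec <- make_sections(n_samples(sub), rate, args$section_s %||% 10)
      m <- fit_var(sub, p, sections = sec)
      ds <- gc_spectrum(m)
      band_integral(ds, args$direction %||% "1->2", band)
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.metric_timecourse <- function(x, ...) {
  cat(sprintf("<metric_timecourse> %s/%s: %d bins of %g s, slope %.4g per min\n",
              x$metric, x$band, length(x$values), x$bin_s, x$slope))
  invisible(x)
}
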