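# Plain-text dataset exchange: recordings and spike trains as CSV,
# scenario configs as YAML, run manifests as JSON.

#' Write / read a recording as CSV
#'
#' One row per sample, one column per channel; metadata (rate, labels,
#' reference) in a `# key: value` comment header.
#'
#' @param rec an `lfp_recording`.
#' @param path output file.
#' @export
write_recording_csv <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# rate_hz: %.10g", rec$rate_hz),
               sprintf("# reference: %s", rec$reference)), con)
  df <- as.data.frame(t(rec$data))
  names(df) <- rec$labels
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @param path file written by [write_recording_csv()].
#' @return the `lfp_recording`.
#' @export
read_recording_csv <- function(path) {
  hdr <- readLines(path, n = 2)
  rate <- as.numeric(sub("# rate_hz: ", "", hdr[1]))
  ref <- sub("# reference: ", "", hdr[2])
  df <- utils::read.csv(path, comment.char = "#")
  lfp_recording(t(as.matrix(df)), rate, names(df), ref)
}

#' Write a spike train as CSV
#' @param spikes a `spike_train`.
#' @param path output file.
#' @export
write_spikes_csv <- function(spikes, path) {
  utils::write.csv(data.frame(time_s = spikes$times), path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a scenario / pipeline config from YAML
#' @param path YAML file.
#' @return named list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' Write a JSON run manifest
#' @param manifest named list (parameters, seeds, versions).
#' @param path output file.
#' @export
write_manifest <- function(manifest, path) {
  manifest$package_version <-
    as.character(utils::packageVersion("lfpcoupling"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
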