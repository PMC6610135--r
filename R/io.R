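# On-disk formats: headered TSV for membrane-potential containers and spike
# event lists, JSON for run manifests. Round-trips are exact to the printed
# precision (full double precision is written).

#' Write / read a membrane-potential container
#'
#' Tab-separated text with commented header lines carrying the sampling
#' rate and time origin, a `time` column in seconds, and one column per
#' cell in mV. A file without a sampling-rate header is rejected.
#'
#' @param x A `vm_traces` object.
#' @param path File path.
#' @return `read_vm_traces()` returns a `vm_traces`.
#' @export
write_vm_traces <- function(x, path) {
  stopifnot(inherits(x, "vm_traces"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# vm_traces\n# sampling_rate_hz: %.10g\n# t0_s: %.10g",
                     x$fs, x$t0), con)
  df <- data.frame(time = x$t0 + (seq_len(nrow(x$vm)) - 1) / x$fs, x$vm,
                   check.names = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_vm_traces
#' @export
read_vm_traces <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  rate_line <- grep("^# sampling_rate_hz:", hdr, value = TRUE)
  if (!length(rate_line)) {
    abort("Malformed vm file: missing '# sampling_rate_hz:' header.")
  }
  fs <- as.numeric(sub("^# sampling_rate_hz:\\s*", "", rate_line[1]))
  t0_line <- grep("^# t0_s:", hdr, value = TRUE)
  t0 <- if (length(t0_line)) as.numeric(sub("^# t0_s:\\s*", "", t0_line[1])) else 0
  df <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                          sep = "\t", check.names = FALSE)
  vm <- as.matrix(df[, setdiff(names(df), "time"), drop = FALSE])
  new_vm_traces(vm, fs = fs, t0 = t0, cells = colnames(vm))
}

#' Write / read spike event lists
#'
#' Two-column tab-separated events (`unit`, `time` in seconds) with a
#' commented header listing the recording interval and the full unit roster
#' (so units with no events survive a round trip). Times are sorted per
#' unit on read (with a warning if the file was unsorted); negative times
#' are rejected.
#'
#' @param x A `spike_trains` tibble.
#' @param path File path.
#' @return `read_spike_events()` returns a `spike_trains`.
#' @export
write_spike_events <- function(x, path) {
  iv <- attr(x, "interval")
  units <- attr(x, "units")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# spike_trains\n# interval_s: %.10g %.10g\n# units: %s",
                     iv[1], iv[2], paste(units, collapse = ",")), con)
  utils::write.table(
    data.frame(unit = x$unit, time = format(x$time, digits = 17, trim = TRUE,
                                            scientific = FALSE)),
    con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spike_events
#' @export
read_spike_events <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  iv_line <- grep("^# interval_s:", hdr, value = TRUE)
  if (!length(iv_line)) abort("Malformed spike file: missing interval header.")
  iv <- as.numeric(strsplit(sub("^# interval_s:\\s*", "", iv_line[1]), " ")[[1]])
  units_line <- grep("^# units:", hdr, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.table(text = body, header = TRUE, sep = "\t")
  if (any(df$time < 0)) abort("Malformed spike file: negative spike times.")
  unsorted <- any(vapply(split(df$time, df$unit), is.unsorted, logical(1)))
  if (unsorted) warn("Spike times were not sorted within units; sorting on read.")
  units <- if (length(units_line)) {
    as.integer(strsplit(sub("^# units:\\s*", "", units_line[1]), ",")[[1]])
  } else NULL
  new_spike_trains(df$unit, df$time, interval = iv, units = units)
}

#' Write a run manifest
#'
#' Records the configuration snapshot, seed, package version and output
#' files of a workflow run as JSON, so a run can be reproduced exactly.
#'
#' @param path Manifest path.
#' @param config Configuration list (echoed verbatim).
#' @param seed Master seed of the run.
#' @param files Character vector of output files.
#' @return The manifest list, invisibly.
#' @export
write_run_manifest <- function(path, config, seed, files = character()) {
  manifest <- list(
    package = "cpgnet",
    version = as.character(utils::packageVersion("cpgnet")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    config = config,
    files = files)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
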