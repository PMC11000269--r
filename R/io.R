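# Plain-text I/O: CSV signal/annotation/cohort files and run manifests.

#' Write / read an ECG signal as CSV
#'
#' Signal CSV has header `sample,mV` (0-based sample index, amplitude in
#' mV); the sampling rate travels in a sidecar manifest or is supplied on
#' read.
#'
#' @param record an [ecg_record()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ecg_csv <- function(record, path) {
  stopifnot(inherits(record, "ecg_record"))
  utils::write.csv(data.frame(sample = seq_along(record$samples) - 1L,
                              mV = record$samples),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ecg_csv
#' @param fs sampling rate in Hz of the stored signal.
#' @param lead_name lead label.
#' @export
read_ecg_csv <- function(path, fs, lead_name = "CM2") {
  d <- utils::read.csv(path)
  stopifnot(all(c("sample", "mV") %in% names(d)))
  ecg_record(d$mV[order(d$sample)], fs = fs, lead_name = lead_name)
}

#' Write / read a beat annotation as CSV
#'
#' Annotation CSV has header `sample,label` (0-based R-peak sample index).
#'
#' @param annotation data frame with `sample` and `label` columns.
#' @param path file path.
#' @return `path` (write) or the annotation data frame (read).
#' @export
write_annotation_csv <- function(annotation, path) {
  stopifnot(all(c("sample", "label") %in% names(annotation)))
  utils::write.csv(annotation[, c("sample", "label")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_annotation_csv
#' @export
read_annotation_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "label") %in% names(d)))
  d[order(d$sample), c("sample", "label")]
}

#' Write a run manifest
#'
#' JSON provenance record written next to every pipeline output: the
#' configuration used, the seed, package and R versions, and the md5 of each
#' output file, so any artifact is regenerable from configuration + seed.
#'
#' @param path manifest file path.
#' @param config named list of configuration values.
#' @param seed the seed used.
#' @param outputs character vector of output file paths to fingerprint.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(path, config, seed, outputs = character(0)) {
  man <- list(
    package = "holterscan",
    package_version = as.character(utils::packageVersion("holterscan")),
    r_version = R.version.string,
    seed = seed,
    config = config,
    outputs = lapply(stats::setNames(outputs, basename(outputs)), function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    }))
  writeLines(jsonlite::toJSON(man, auto_unbox = TRUE, digits = NA, pretty = TRUE),
             path)
  invisible(man)
}

#' Write / read a paired-window cohort count table as CSV
#'
#' @param cohort a [simulate_cohort()] result (or compatible data frame).
#' @param path file path.
#' @return `path` (write) or the cohort data frame with window attributes
#'   restored (read).
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @param window_short,window_long window lengths in hours to attach.
#' @export
read_cohort_csv <- function(path, window_short = 2, window_long = 24) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  attr(d, "window_short") <- window_short
  attr(d, "window_long") <- window_long
  d
}
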