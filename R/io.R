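#' Read epochs from a canonical manifest
#'
#' The canonical on-disk fixture format is a JSON manifest naming the sampling
#' rate, onset index, channel list and one `(file, label)` entry per trial,
#' with each trial stored as a headerless comma-separated matrix (row =
#' channel, values in microvolts). Paths in the manifest are resolved relative
#' to the manifest's directory.
#'
#' @param manifest_path path to `manifest.json`.
#' @return an [epoch_set()] with trials in manifest order.
#' @export
read_epochs <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop("manifest not found: ", manifest_path)
  man <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  for (f in c("sampling_rate_hz", "onset_index", "channels", "trials"))
    if (is.null(man[[f]])) stop("manifest missing required field: ", f)
  base <- dirname(manifest_path)
  channels <- unlist(man$channels)
  nchan <- length(channels)
  trials <- vector("list", length(man$trials))
  labels <- character(length(man$trials))
  for (i in seq_along(man$trials)) {
    entry <- man$trials[[i]]
    path <- file.path(base, entry$file)
    if (!file.exists(path))
      stop(sprintf("trial %d: CSV not found: %s", i, path))
    lines <- readLines(path)
    rows <- strsplit(lines, ",", fixed = TRUE)
    lens <- lengths(rows)
    if (length(rows) != nchan || length(unique(lens)) != 1)
      stop(sprintf("trial %d (%s): ragged or wrong dimensions (%d rows, widths %s; expected %d rows)",
                   i, entry$file, length(rows),
                   paste(unique(lens), collapse = "/"), nchan))
    m <- matrix(as.numeric(unlist(rows)), nrow = nchan, byrow = TRUE)
    if (anyNA(m))
      stop(sprintf("trial %d (%s): non-numeric values", i, entry$file))
    trials[[i]] <- m
    labels[i] <- as.character(entry$label)
  }
  # trials may be empty but channel list can still be typed
  es <- epoch_set(trials, labels, channels,
                  sampling_rate = man$sampling_rate_hz,
                  onset_index = if (is.null(man$onset_index) || is.na(man$onset_index))
                    NA_integer_ else man$onset_index,
                  band_tag = if (is.null(man$band_tag)) "whole" else man$band_tag)
  if (n_trials(es) > 0 && n_channels(es) != nchan)
    stop("channel count mismatch between manifest and CSV matrices")
  es
}

#' Write epochs in the canonical manifest + CSV format
#'
#' Values are written as decimal text at 10 significant digits, which
#' round-trips through [read_epochs()] bit-exactly at that precision.
#'
#' @param epochs an [epoch_set()].
#' @param out_dir output directory; created if absent.
#' @return path to the written `manifest.json`, invisibly.
#' @export
write_epochs <- function(epochs, out_dir) {
  validate_epoch_set(epochs)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n <- n_trials(epochs)
  files <- sprintf("trial_%04d.csv", seq_len(n))
  for (i in seq_len(n)) {
    m <- epochs$trials[[i]]
    lines <- apply(m, 1, function(r) paste(sprintf("%.10g", r), collapse = ","))
    writeLines(lines, file.path(out_dir, files[i]))
  }
  man <- list(
    format_version = 1L,
    sampling_rate_hz = epochs$sampling_rate,
    onset_index = epochs$onset_index,
    band_tag = epochs$band_tag,
    channels = as.list(epochs$channel_names),
    trials = lapply(seq_len(n), function(i)
      list(file = files[i], label = epochs$labels[i])))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Import an epoched EEGLAB dataset
#'
#' Adapter for EEGLAB `.set` files (MATLAB container). The file is converted
#' to the canonical manifest format via the bundled Python helper (which uses
#' scipy's MAT reader) and then read back with [read_epochs()]. Event codes
#' are mapped to the label alphabet through `event_map`; an unmapped code is
#' an error listing all codes found. Continuous (non-epoched) datasets are
#' rejected with a pointer to [segment_epochs()].
#'
#' Data are assumed to be stored in microvolts, EEGLAB's native unit.
#'
#' @param path path to an epoched `.set` file with embedded data.
#' @param event_map named character vector mapping event codes to labels,
#'   e.g. `c("1" = "Ug", "2" = "Tg", "3" = "Sc")`. `NULL` keeps raw codes.
#' @param python python interpreter to use (needs scipy + numpy).
#' @return an [epoch_set()].
#' @export
import_eeglab_set <- function(path, event_map = NULL, python = "python") {
  if (!file.exists(path)) stop(".set file not found: ", path)
  script <- system.file("python", "eeglab_to_canonical.py", package = "dspline")
  if (script == "") stop("bundled converter script not found")
  out_dir <- tempfile("eeglab_import_")
  res <- suppressWarnings(system2(python, c(shQuote(script), shQuote(path), shQuote(out_dir)),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status")
  if (!is.null(status) && status != 0) {
    msg <- paste(res, collapse = "\n")
    if (grepl("CONTINUOUS", msg))
      stop("dataset is continuous, not epoched; segment it first with segment_epochs()")
    stop("EEGLAB import failed:\n", msg)
  }
  es <- read_epochs(file.path(out_dir, "manifest.json"))
  if (!is.null(event_map)) {
    unknown <- setdiff(unique(es$labels), names(event_map))
    if (length(unknown) > 0)
      stop("event code(s) not in mapping: ", paste(unknown, collapse = ", "))
    es$labels <- unname(event_map[es$labels])
  }
  es
}
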