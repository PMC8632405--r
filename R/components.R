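#' Default ERP component latency table
#'
#' The five components whose time courses carry intention-related information:
#' N70, P120 and P300 are point latencies sampled in a small symmetric window;
#' N170-P200 and P400-700 are inclusive latency ranges. Latencies are in ms
#' relative to stimulus onset.
#'
#' @return data frame with columns `name`, `type` (`point`/`range`),
#'   `center_ms`, `lo_ms`, `hi_ms`.
#' @export
default_component_table <- function() {
  data.frame(
    name = c("N70", "P120", "N170_P200", "P300", "P400_700"),
    type = c("point", "point", "range", "point", "range"),
    center_ms = c(70, 120, NA, 300, NA),
    lo_ms = c(NA, NA, 170, NA, 400),
    hi_ms = c(NA, NA, 200, NA, 700),
    stringsAsFactors = FALSE)
}

#' ERP component sample windows
#'
#' Converts the component latency table into 0-based half-open sample ranges
#' in trial coordinates. Point components occupy `2 * half_width + 1` samples
#' centred on the nominal latency (the default `half_width = 2` gives the
#' conventional 5-sample window); range components include every sample whose
#' latency falls in the inclusive ms range. ms-to-sample conversion is
#' round-to-nearest.
#'
#' At 500 Hz with the defaults the five windows hold 5/5/16/5/151 samples,
#' a combined length of 182.
#'
#' @param rate sampling rate in Hz.
#' @param onset_index 0-based sample index of stimulus onset.
#' @param n_samples trial length in samples (for bounds checking).
#' @param half_width half-width of point-component windows, in samples.
#' @param table latency table in the format of [default_component_table()].
#' @return object of class `ComponentWindows`: data frame with columns
#'   `name`, `start`, `end` (0-based half-open) plus attribute
#'   `combined_length`.
#' @export
component_windows <- function(rate, onset_index, n_samples,
                              half_width = 2L, table = default_component_table()) {
  stopifnot(rate > 0, onset_index >= 0)
  ms_to_samp <- function(ms) as.integer(round(ms / 1000 * rate))
  rows <- lapply(seq_len(nrow(table)), function(i) {
    r <- table[i, ]
    if (r$type == "point") {
      center <- onset_index + ms_to_samp(r$center_ms)
      data.frame(name = r$name, start = center - half_width,
                 end = center + half_width + 1L)
    } else {
      data.frame(name = r$name,
                 start = onset_index + ms_to_samp(r$lo_ms),
                 end = onset_index + ms_to_samp(r$hi_ms) + 1L)
    }
  })
  w <- do.call(rbind, rows)
  bad <- w$start < 0 | w$end > n_samples
  if (any(bad))
    stop("component window(s) out of trial bounds: ",
         paste(w$name[bad], collapse = ", "))
  if (is.unsorted(w$start)) w <- w[order(w$start), ]
  structure(w, combined_length = sum(w$end - w$start),
            class = c("ComponentWindows", "data.frame"))
}

#' Combined length of a set of component windows
#' @param windows a [component_windows()] object.
#' @return total sample count of the concatenated windows.
#' @export
combined_length <- function(windows) attr(windows, "combined_length")

#' Extract and concatenate ERP component windows
#'
#' Each trial matrix (N x T) is reduced to N x T' by concatenating the
#' component window slices in chronological order, discarding everything
#' outside the windows. This removes redundant samples and shrinks the
#' vectorized dimension the spatial-pattern model has to handle. The result's
#' `onset_index` is set to `NA` because the concatenated columns are no
#' longer a contiguous time axis.
#'
#' @param epochs an [epoch_set()].
#' @param windows a [component_windows()] object valid for these epochs.
#' @return `EpochSet` of recombined trials; the windows used are attached as
#'   attribute `component_windows`.
#' @export
extract_combine <- function(epochs, windows) {
  validate_epoch_set(epochs)
  stopifnot(inherits(windows, "ComponentWindows"))
  if (max(windows$end) > n_samples(epochs))
    stop("windows exceed trial length")
  cols <- unlist(lapply(seq_len(nrow(windows)), function(i)
    (windows$start[i] + 1L):windows$end[i]))
  out <- epochs
  out$trials <- lapply(epochs$trials, function(m) m[, cols, drop = FALSE])
  out$onset_index <- NA_integer_
  attr(out, "component_windows") <- windows
  out
}
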