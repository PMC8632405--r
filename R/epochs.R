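#' Labeled collection of EEG epochs
#'
#' An `EpochSet` holds `n` single-trial EEG matrices (channels x samples,
#' microvolts) together with per-trial condition labels, channel names,
#' sampling rate, the sample index of stimulus onset and a tag naming the
#' frequency band the data carry. All trials must share the same dimensions.
#'
#' Sample indices throughout the public API are 0-based: `onset_index = 100`
#' means the 101st stored sample is the stimulus onset. The label alphabet is
#' open; the three intention conditions `Ug` (use), `Tg` (transport) and `Sc`
#' (simple contact) are only the default vocabulary of the pipeline driver.
#'
#' @param trials list of numeric matrices, each N channels x T samples, in
#'   microvolts.
#' @param labels character vector of per-trial condition codes, one per trial.
#' @param channel_names character vector of N channel names; autogenerated
#'   (`ch01`, `ch02`, ...) when `NULL`.
#' @param sampling_rate sampling rate in Hz (default 500).
#' @param onset_index 0-based sample index of stimulus onset within each
#'   trial; `NA` marks trial matrices whose columns are no longer a contiguous
#'   time axis (e.g. after [extract_combine()]).
#' @param band_tag identifier of the frequency band this set carries.
#' @return object of class `EpochSet`.
#' @seealso [read_epochs()], [write_epochs()], [simulate_epochs()]
#' @export
#' @examples
#' es <- epoch_set(list(matrix(0, 2, 10), matrix(1, 2, 10)), c("Ug", "Sc"))
#' n_trials(es)
epoch_set <- function(trials, labels, channel_names = NULL,
                      sampling_rate = 500, onset_index = 0L,
                      band_tag = "whole") {
  if (!is.list(trials)) stop("`trials` must be a list of matrices")
  trials <- lapply(trials, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  n <- length(trials)
  if (n > 0) {
    nc <- nrow(trials[[1]])
    if (is.null(channel_names)) channel_names <- sprintf("ch%02d", seq_len(nc))
  } else if (is.null(channel_names)) {
    channel_names <- character(0)
  }
  x <- structure(
    list(trials = trials,
         labels = as.character(labels),
         channel_names = as.character(channel_names),
         sampling_rate = as.numeric(sampling_rate),
         onset_index = if (is.na(onset_index)) NA_integer_ else as.integer(onset_index),
         band_tag = as.character(band_tag)),
    class = "EpochSet")
  validate_epoch_set(x)
  x
}

#' Validate an EpochSet
#'
#' Checks the structural invariants: all trials share identical dimensions,
#' labels align with trials, the onset index lies inside the trial (unless
#' `NA`) and the sampling rate is positive. Violations are errors, never
#' silently repaired.
#'
#' @param x an `EpochSet`.
#' @return `x`, invisibly, if valid.
#' @export
validate_epoch_set <- function(x) {
  stopifnot(inherits(x, "EpochSet"))
  n <- length(x$trials)
  if (length(x$labels) != n)
    stop(sprintf("labels (%d) do not align with trials (%d)", length(x$labels), n))
  if (!is.finite(x$sampling_rate) || x$sampling_rate <= 0)
    stop("sampling_rate must be > 0")
  if (n > 0) {
    nc <- nrow(x$trials[[1]])
    ns <- ncol(x$trials[[1]])
    for (i in seq_len(n)) {
      if (nrow(x$trials[[i]]) != nc || ncol(x$trials[[i]]) != ns)
        stop(sprintf(
          "trial %d has dimensions %dx%d but trial 1 has %dx%d",
          i, nrow(x$trials[[i]]), ncol(x$trials[[i]]), nc, ns))
    }
    if (length(x$channel_names) != nc)
      stop(sprintf("channel_names (%d) do not match channel count (%d)",
                   length(x$channel_names), nc))
    if (!is.na(x$onset_index) && (x$onset_index < 0 || x$onset_index >= ns))
      stop(sprintf("onset_index %d outside [0, %d)", x$onset_index, ns))
  }
  invisible(x)
}

#' @export
print.EpochSet <- function(x, ...) {
  cat(sprintf("<EpochSet> %d trials", n_trials(x)))
  if (n_trials(x) > 0)
    cat(sprintf(", %d channels x %d samples @ %g Hz", n_channels(x),
                n_samples(x), x$sampling_rate))
  cat(sprintf(", band '%s'\n", x$band_tag))
  if (n_trials(x) > 0) {
    tab <- table(x$labels)
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
    cat(sprintf("  onset_index: %s\n",
                if (is.na(x$onset_index)) "NA (recombined)" else x$onset_index))
  }
  invisible(x)
}

#' Number of trials in an EpochSet
#' @param x an `EpochSet`.
#' @return integer count.
#' @export
n_trials <- function(x) length(x$trials)

#' Number of channels in an EpochSet
#' @param x an `EpochSet`.
#' @return integer count (0 when empty).
#' @export
n_channels <- function(x) if (n_trials(x) == 0) 0L else nrow(x$trials[[1]])

#' Number of samples per trial in an EpochSet
#' @param x an `EpochSet`.
#' @return integer count (0 when empty).
#' @export
n_samples <- function(x) if (n_trials(x) == 0) 0L else ncol(x$trials[[1]])

#' Subset the trials of an EpochSet
#'
#' @param x an `EpochSet`.
#' @param idx integer or logical index into the trials.
#' @return a new `EpochSet` with the selected trials, metadata unchanged.
#' @export
subset_epochs <- function(x, idx) {
  epoch_set(x$trials[idx], x$labels[idx], x$channel_names,
            x$sampling_rate, x$onset_index, x$band_tag)
}

#' Frequency band definition
#'
#' @param name band identifier, conventionally one of `delta`, `theta`,
#'   `alpha`, `beta`, `whole`.
#' @param low_hz,high_hz band edges in Hz, `0 < low_hz < high_hz`.
#' @return object of class `BandDefinition`.
#' @export
band_definition <- function(name, low_hz, high_hz) {
  if (!(low_hz > 0 && low_hz < high_hz))
    stop("band edges must satisfy 0 < low_hz < high_hz")
  structure(list(name = as.character(name), low_hz = low_hz, high_hz = high_hz),
            class = "BandDefinition")
}

#' Standard EEG band table
#'
#' The conventional band edges consistent with a 1-30 Hz broadband analysis:
#' delta 1-4, theta 4-8, alpha 8-13, beta 13-30 and the whole band 1-30 Hz.
#'
#' @param names optional subset of band names to return.
#' @return named list of [band_definition()] objects.
#' @export
eeg_bands <- function(names = c("delta", "theta", "alpha", "beta", "whole")) {
  all <- list(
    delta = band_definition("delta", 1, 4),
    theta = band_definition("theta", 4, 8),
    alpha = band_definition("alpha", 8, 13),
    beta  = band_definition("beta", 13, 30),
    whole = band_definition("whole", 1, 30))
  unknown <- setdiff(names, names(all))
  if (length(unknown) > 0)
    stop("unknown band name(s): ", paste(unknown, collapse = ", "))
  all[names]
}
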