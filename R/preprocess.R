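#' Cut continuous multichannel data into stimulus-locked epochs
#'
#' Each event yields one trial of `T = round((pre_ms + post_ms)/1000 * rate) + 1`
#' samples with `onset_index = round(pre_ms/1000 * rate)`. Events whose window
#' does not fit inside the recording are skipped with a warning and listed in
#' the segmentation report attached to the result.
#'
#' @param continuous numeric matrix, channels x samples.
#' @param events data frame (or list of pairs) with columns `sample` (0-based
#'   sample index of the event) and `label`.
#' @param pre_ms,post_ms epoch span before/after the event, in ms.
#' @param rate sampling rate in Hz.
#' @param channel_names optional channel names.
#' @return an [epoch_set()]; `attr(, "segmentation_report")` holds the kept
#'   and skipped event indices.
#' @export
segment_epochs <- function(continuous, events, pre_ms, post_ms, rate,
                           channel_names = NULL) {
  continuous <- as.matrix(continuous)
  if (is.list(events) && !is.data.frame(events))
    events <- data.frame(sample = vapply(events, `[[`, numeric(1), 1),
                         label = vapply(events, function(e) as.character(e[[2]]), ""))
  Tn <- as.integer(round((pre_ms + post_ms) / 1000 * rate)) + 1L
  onset <- as.integer(round(pre_ms / 1000 * rate))
  S <- ncol(continuous)
  starts <- as.integer(events$sample) - onset      # 0-based start of each epoch
  ok <- starts >= 0L & (starts + Tn - 1L) <= (S - 1L)
  if (any(!ok))
    warning(sprintf("%d event(s) too close to a recording edge were skipped: %s",
                    sum(!ok), paste(which(!ok), collapse = ", ")))
  trials <- lapply(starts[ok], function(s0)
    continuous[, (s0 + 1L):(s0 + Tn), drop = FALSE])
  es <- epoch_set(trials, as.character(events$label)[ok], channel_names,
                  sampling_rate = rate, onset_index = onset)
  attr(es, "segmentation_report") <- list(
    n_events = nrow(events), kept = which(ok), skipped = which(!ok))
  es
}

#' Amplitude-threshold artifact rejection
#'
#' Retains exactly the trials whose every sample lies within
#' `[-threshold_uv, +threshold_uv]` microvolts, bounds inclusive (a sample at
#' exactly the threshold is kept). The conventional threshold is 75 uV.
#'
#' @param epochs an [epoch_set()].
#' @param threshold_uv positive rejection threshold in microvolts.
#' @return list with `epochs` (the survivors) and `report` (removed trial
#'   indices, kept indices, surviving counts per class).
#' @export
reject_artifacts <- function(epochs, threshold_uv = 75) {
  validate_epoch_set(epochs)
  if (!(threshold_uv > 0)) stop("threshold_uv must be > 0")
  peak <- vapply(epochs$trials, function(m) max(abs(m)), numeric(1))
  keep <- peak <= threshold_uv
  survivors <- subset_epochs(epochs, keep)
  report <- list(
    threshold_uv = threshold_uv,
    removed = which(!keep),
    kept = which(keep),
    surviving_by_class = as.list(table(survivors$labels)))
  list(epochs = survivors, report = report)
}

#' Baseline correction
#'
#' Subtracts, per trial and per channel, the channel's mean over the baseline
#' range. The default baseline is the full pre-stimulus span
#' `[0, onset_index)`.
#'
#' @param epochs an [epoch_set()] with a valid `onset_index` (for the default
#'   baseline).
#' @param baseline length-2 integer vector `(start, end)`: 0-based, half-open
#'   sample range. Must be non-empty and lie within `[0, onset_index]`.
#' @return baseline-corrected `EpochSet`.
#' @export
baseline_correct <- function(epochs, baseline = NULL) {
  validate_epoch_set(epochs)
  if (is.null(baseline)) {
    if (is.na(epochs$onset_index))
      stop("no onset_index available; pass an explicit baseline range")
    baseline <- c(0L, epochs$onset_index)
  }
  start <- as.integer(baseline[1])
  end <- as.integer(baseline[2])
  if (end <= start) stop("empty baseline range")
  if (start < 0 || (!is.na(epochs$onset_index) && end > epochs$onset_index))
    stop("baseline range must lie within [0, onset_index]")
  if (end > n_samples(epochs)) stop("baseline range exceeds trial length")
  cols <- (start + 1L):end
  out <- epochs
  out$trials <- lapply(epochs$trials, function(m)
    m - rowMeans(m[, cols, drop = FALSE]))
  out
}
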