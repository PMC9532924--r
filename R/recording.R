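#' Construct an EEG recording
#'
#' The raw signal container used throughout the package: a channels x
#' samples matrix in microvolts with unique channel labels and a sampling
#' rate.
#'
#' @param data numeric matrix, channels x samples, amplitude in uV.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector, one unique label per row of
#'   `data` (10-20 names for scalp recordings, `"A-B"` for bipolar
#'   derivations).
#' @param subject_id identifier carried through the pipeline.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_labels, subject_id = "subject") {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric channels x samples matrix")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a positive scalar")
  }
  if (length(channel_labels) != nrow(data)) {
    stop("one label per channel required")
  }
  if (anyDuplicated(channel_labels)) stop("channel labels must be unique")
  rownames(data) <- channel_labels
  structure(
    list(data = data, fs = fs, channel_labels = as.character(channel_labels),
         subject_id = as.character(subject_id)),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs))
  invisible(x)
}

#' Recording duration in seconds
#' @param recording an `eeg_recording`.
#' @return duration in seconds.
#' @export
recording_duration <- function(recording) {
  ncol(recording$data) / recording$fs
}

#' Construct an epoch set
#'
#' A list of equal-length channels x samples segments cut from one
#' recording, optionally band-filtered and/or in a bipolar montage.
#'
#' @param epochs list of channels x L numeric matrices, identical shapes.
#' @param fs sampling rate in Hz.
#' @param epoch_length_s epoch length in seconds; every epoch must have
#'   exactly `epoch_length_s * fs` samples.
#' @param channel_labels labels shared by all epochs.
#' @param montage_pairs two-column matrix of electrode pairs when the
#'   channels are bipolar derivations, else `NULL`.
#' @param band a [band_definition()] when the epochs are band-filtered,
#'   else `NULL`.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(epochs, fs, epoch_length_s, channel_labels,
                      montage_pairs = NULL, band = NULL) {
  if (!is.list(epochs) || length(epochs) < 1L) stop("need at least one epoch")
  L <- round(epoch_length_s * fs)
  ok <- vapply(epochs, function(e) {
    is.matrix(e) && nrow(e) == length(channel_labels) && ncol(e) == L
  }, logical(1))
  if (!all(ok)) stop("every epoch must be channels x (epoch_length_s * fs)")
  structure(
    list(epochs = epochs, fs = fs, epoch_length_s = epoch_length_s,
         channel_labels = as.character(channel_labels),
         montage_pairs = montage_pairs, band = band),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs x %d channels x %g s @ %g Hz%s\n",
              length(x$epochs), length(x$channel_labels), x$epoch_length_s,
              x$fs,
              if (!is.null(x$band)) paste0(", band ", x$band$name) else ""))
  invisible(x)
}
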