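# windowed-sinc (Kaiser beta 8) rational resampler: upsample by p,
# low-pass at min(Nyquist_in, Nyquist_out), downsample by q, with exact
# linear-phase group-delay compensation
resample_signal <- function(x, p, q) {
  p <- as.integer(p); q <- as.integer(q)
  if (p == q) return(x)
  n <- length(x)
  half <- 10L * max(p, q)
  m <- (-half):half
  cutoff <- 1 / max(p, q)  # relative to the upsampled Nyquist
  h <- ifelse(m == 0L, cutoff, sin(pi * cutoff * m) / (pi * m))
  h <- h * signal::kaiser(2L * half + 1L, 8)
  h <- h / sum(h) * p      # restore unit passband gain after zero-stuffing
  up <- numeric(n * p)
  up[seq(1L, n * p, by = p)] <- x
  y <- stats::filter(c(up, numeric(half)), h, method = "convolution",
                     sides = 1)
  y <- as.numeric(y)[(half + 1L):(n * p + half)]
  y[seq(1L, length(y), by = q)]
}

#' Resample a recording
#'
#' Polyphase (windowed-sinc) rational resampling of every channel to
#' `target_fs`. Duration is preserved to within one sample.
#'
#' @param recording an [eeg_recording()].
#' @param target_fs target sampling rate in Hz (default 500, the pipeline
#'   standard).
#' @param min_fs smallest admissible target: twice the highest configured
#'   band edge (default 2 x 29 Hz).
#' @return The resampled [eeg_recording()].
#' @export
resample_recording <- function(recording, target_fs = 500,
                               min_fs = 2 * max(vapply(eeg_bands(), `[[`,
                                                       numeric(1), "high"))) {
  stopifnot(inherits(recording, "eeg_recording"), target_fs > 0)
  if (target_fs <= min_fs) {
    stop(sprintf("target_fs = %g Hz is at or below twice the highest band edge (%g Hz)",
                 target_fs, min_fs / 2))
  }
  if (target_fs == recording$fs) return(recording)
  # rational approximation via integer-scaled gcd (rates are Hz with at
  # most millihertz resolution)
  a <- round(target_fs * 1000); b <- round(recording$fs * 1000)
  g <- gcd_int(a, b)
  p <- a / g; q <- b / g
  out <- t(apply(recording$data, 1L, resample_signal, p = p, q = q))
  eeg_recording(out, target_fs, recording$channel_labels,
                recording$subject_id)
}

gcd_int <- function(a, b) {
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

#' Derive a bipolar montage
#'
#' Each derived channel is the difference anode - cathode of one electrode
#' pair, labeled `"A-B"`, in the order of `montage_pairs`.
#'
#' @param recording an [eeg_recording()] in a referential montage.
#' @param montage_pairs two-column character matrix of electrode pairs;
#'   defaults to the longitudinal chains of [default_montage()].
#' @return A bipolar [eeg_recording()].
#' @export
to_bipolar <- function(recording, montage_pairs = default_montage()) {
  stopifnot(inherits(recording, "eeg_recording"))
  montage_pairs <- as.matrix(montage_pairs)
  if (ncol(montage_pairs) != 2L) stop("montage_pairs must have two columns")
  unknown <- setdiff(unique(c(montage_pairs)), recording$channel_labels)
  if (length(unknown) > 0) {
    stop("electrode label(s) not in recording: ",
         paste(unknown, collapse = ", "))
  }
  out <- recording$data[montage_pairs[, 1L], , drop = FALSE] -
    recording$data[montage_pairs[, 2L], , drop = FALSE]
  labels <- paste0(montage_pairs[, 1L], "-", montage_pairs[, 2L])
  rec <- eeg_recording(out, recording$fs, labels, recording$subject_id)
  rec$montage_pairs <- montage_pairs
  rec
}

#' Cut a recording into contiguous fixed-length epochs
#'
#' Non-overlapping segments of `epoch_length_s` seconds on half-open
#' sample intervals; a trailing partial epoch is discarded.
#'
#' @param recording an [eeg_recording()].
#' @param epoch_length_s epoch length in seconds (default 2).
#' @return An [epoch_set()].
#' @export
segment_epochs <- function(recording, epoch_length_s = 2) {
  stopifnot(inherits(recording, "eeg_recording"), epoch_length_s > 0)
  L <- round(epoch_length_s * recording$fs)
  n <- ncol(recording$data)
  k <- n %/% L
  if (k < 1L) {
    stop(sprintf("recording (%.2f s) shorter than one epoch (%g s)",
                 n / recording$fs, epoch_length_s))
  }
  epochs <- lapply(seq_len(k), function(i) {
    recording$data[, ((i - 1L) * L + 1L):(i * L), drop = FALSE]
  })
  epoch_set(epochs, recording$fs, epoch_length_s, recording$channel_labels,
            montage_pairs = recording$montage_pairs)
}

#' Amplitude/flatline artifact screen
#'
#' A programmatic stand-in for visual artifact review: an epoch is
#' rejected when any channel's peak absolute amplitude exceeds
#' `amplitude_threshold_uv` (movement/electrode artifacts, large
#' discharges) or any channel's peak-to-peak range falls below
#' `flatline_eps` (disconnected channel). Kept epochs are returned
#' unaltered.
#'
#' @param epochs an [epoch_set()].
#' @param amplitude_threshold_uv rejection threshold in uV (default 200).
#' @param flatline_eps minimum channel range in uV (default 0.1).
#' @return The screened [epoch_set()], with attributes `rejected` (indices
#'   of removed epochs) and `rejection_log` (per-epoch reason, `NA` if
#'   kept).
#' @export
reject_artifacts <- function(epochs, amplitude_threshold_uv = 200,
                             flatline_eps = 0.1) {
  stopifnot(inherits(epochs, "epoch_set"),
            amplitude_threshold_uv > 0, flatline_eps > 0)
  reason <- vapply(epochs$epochs, function(e) {
    if (max(abs(e)) > amplitude_threshold_uv) return("amplitude")
    rng <- apply(e, 1L, function(ch) diff(range(ch)))
    if (any(rng < flatline_eps)) return("flatline")
    NA_character_
  }, character(1))
  keep <- is.na(reason)
  if (!any(keep)) {
    stop("all epochs rejected: insufficient clean data")
  }
  out <- epoch_set(epochs$epochs[keep], epochs$fs, epochs$epoch_length_s,
                   epochs$channel_labels, epochs$montage_pairs, epochs$band)
  attr(out, "rejected") <- which(!keep)
  attr(out, "rejection_log") <- reason
  out
}

# zero-phase Butterworth band-pass of one vector with reflective padding.
# The forward-backward pass of an order-n Butterworth has the purely real
# transfer |H(f)|^2 = 1 / (1 + Omega(f)^(2n)) with
# Omega(f) = (f^2 - f_lo*f_hi) / (f * (f_hi - f_lo)); applying that gain in
# the FFT domain is the zero-phase filter itself, without the transient
# handling (and cost) of a time-domain filtfilt.
bandpass_vector <- function(x, band, fs, order = 4L) {
  ny <- fs / 2
  if (band$high >= ny) {
    stop(sprintf("band %s upper edge %g Hz incompatible with fs %g Hz",
                 band$name, band$high, fs))
  }
  n <- length(x)
  # reflective padding of >= 3 time constants of the band's lower edge,
  # capped by the segment length
  pad <- min(n - 1L, ceiling(3 * fs / band$low))
  xp <- c(rev(x[2L:(pad + 1L)]), x, rev(x[(n - pad):(n - 1L)]))
  n2 <- length(xp)
  k <- 0:(n2 - 1L)
  f <- pmin(k, n2 - k) * fs / n2
  om2n <- ifelse(f == 0, Inf,
                 ((f^2 - band$low * band$high) /
                    (f * (band$high - band$low)))^(2L * order))
  gain <- 1 / (1 + om2n)
  y <- Re(stats::fft(stats::fft(xp) * gain, inverse = TRUE) / n2)
  y[(pad + 1L):(pad + n)]
}

#' Band-pass filter an epoch set
#'
#' Zero-phase 4th-order Butterworth band-pass applied per channel per
#' epoch: the squared Butterworth magnitude response (the transfer of a
#' forward-backward pass) is applied as a real FFT-domain gain on
#' reflectively padded segments (padding of at least three filter time
#' constants, so epoch edges do not contaminate the phase estimates).
#' Zero phase is essential here: the downstream metrics live entirely in
#' the phase.
#'
#' @param epochs an [epoch_set()].
#' @param band a [band_definition()].
#' @param order Butterworth order (default 4).
#' @return The filtered [epoch_set()] with `band` recorded on it.
#' @export
bandpass_epochs <- function(epochs, band, order = 4L) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(band, "band_definition"))
  filtered <- lapply(epochs$epochs, function(e) {
    t(apply(e, 1L, bandpass_vector, band = band, fs = epochs$fs,
            order = order))
  })
  epoch_set(filtered, epochs$fs, epochs$epoch_length_s,
            epochs$channel_labels, epochs$montage_pairs, band)
}
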