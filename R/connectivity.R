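#' Analytic signal via the Hilbert transform
#'
#' FFT implementation: negative frequencies are zeroed, positive doubled,
#' so the real part of the result equals the input and the imaginary part
#' is its Hilbert transform. The argument of the analytic signal is the
#' instantaneous phase.
#'
#' @param x numeric vector (a band-filtered signal).
#' @return Complex vector of the same length. If the input is constant the
#'   phase is undefined and the result carries attribute
#'   `degenerate = TRUE`.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  if (n == 0L) stop("zero-length input")
  degenerate <- diff(range(x)) == 0
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2 + 1L] <- 1
    h[2L:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    if (n > 1L) h[2L:((n + 1L) / 2)] <- 2
  }
  z <- stats::fft(X * h, inverse = TRUE) / n
  if (degenerate) attr(z, "degenerate") <- TRUE
  z
}

#' Instantaneous phase of a signal
#'
#' @param x numeric vector, or a complex analytic signal as returned by
#'   [analytic_signal()].
#' @return Phase series in radians, wrapped to (-pi, pi\].
#' @export
instantaneous_phase <- function(x) {
  if (is.complex(x)) Arg(x) else Arg(analytic_signal(x))
}

# wrap angles to (-pi, pi]
wrap_phase <- function(d) {
  d <- d %% (2 * pi)
  d[d > pi] <- d[d > pi] - 2 * pi
  d
}

#' Phase-locking value
#'
#' Modulus of the time-averaged unit phasor of the phase difference.
#' 1 means the phase difference is constant over the whole series; a
#' uniformly distributed phase difference gives 0 in expectation.
#'
#' @param phase_a,phase_b equal-length phase series in radians.
#' @return Scalar in \[0, 1\].
#' @export
plv <- function(phase_a, phase_b) {
  if (length(phase_a) != length(phase_b)) stop("length mismatch")
  Mod(mean(exp(1i * (phase_a - phase_b))))
}

#' Phase lag index
#'
#' Absolute mean sign of the wrapped phase difference. Insensitive to
#' zero-lag coupling: a constant difference of 0 (or pi) gives 0, a
#' constant difference that is neither gives 1. Wrapping convention:
#' (-pi, pi\] with sign(0) = 0, and the sign at exactly pi is also taken
#' as 0 (a pi lag is phase-indeterminate in the same way a zero lag is).
#'
#' @param phase_a,phase_b equal-length phase series in radians.
#' @return Scalar in \[0, 1\].
#' @export
pli <- function(phase_a, phase_b) {
  if (length(phase_a) != length(phase_b)) stop("length mismatch")
  d <- wrap_phase(phase_a - phase_b)
  s <- sign(d)
  s[d == pi] <- 0
  abs(mean(s))
}

#' Weighted phase lag index
#'
#' Imaginary-cross-spectrum weighted variant of the PLI (population,
#' non-debiased form): `|mean(Im S)| / mean(|Im S|)` with
#' `S(t) = a(t) * Conj(b(t))`. Near-zero-lag samples contribute with small
#' weight, which removes the PLI's discontinuity around zero lag.
#'
#' @param analytic_a,analytic_b equal-length complex analytic signals.
#' @return Scalar in \[0, 1\]. When every `Im S` is exactly zero (e.g., a
#'   signal against itself) the statistic is undefined; 0 is returned with
#'   attribute `degenerate = TRUE`.
#' @export
wpli <- function(analytic_a, analytic_b) {
  if (length(analytic_a) != length(analytic_b)) stop("length mismatch")
  im <- Im(analytic_a * Conj(analytic_b))
  den <- mean(abs(im))
  if (den == 0) return(structure(0, degenerate = TRUE))
  abs(mean(im)) / den
}

# trim a fraction of samples from each end of an epoch (Hilbert edge
# artifact suppression)
trim_indices <- function(n, trim) {
  k <- floor(n * trim)
  if (2L * k >= n) stop("trim fraction leaves no samples")
  (k + 1L):(n - k)
}

#' Global (mean) pairwise synchronization of an epoch set
#'
#' Computes one of PLV / PLI / wPLI for every unordered channel pair in
#' every epoch, averages each pair over epochs, then averages the pair
#' values (unweighted) into a single global scalar. The first and last
#' `trim` fraction of each epoch's samples are discarded before the
#' metric is taken, to suppress Hilbert edge artifacts.
#'
#' @param epochs a band-filtered [epoch_set()] with >= 2 channels.
#' @param metric `"plv"`, `"pli"` or `"wpli"`.
#' @param trim fraction trimmed from each epoch end (default 0.1).
#' @return A list with `value` (the global mean), `pairs` (the symmetric
#'   pair matrix, `NA` diagonal), `metric`, `band`, `n_epochs_used` and
#'   `n_degenerate` (count of degenerate pair-epochs, wPLI only).
#' @export
global_metric <- function(epochs, metric = c("plv", "pli", "wpli"),
                          trim = 0.1) {
  metric <- match.arg(metric)
  all_metrics(epochs, metric, trim)[[metric]]
}

# shared engine: one Hilbert pass per channel/epoch serves all requested
# metrics
all_metrics <- function(epochs, metrics = c("plv", "pli", "wpli"),
                        trim = 0.1) {
  stopifnot(inherits(epochs, "epoch_set"))
  nc <- length(epochs$channel_labels)
  if (nc < 2L) stop("need at least 2 channels")
  if (length(epochs$epochs) < 1L) stop("no epochs")
  acc <- lapply(metrics, function(m) matrix(0, nc, nc))
  names(acc) <- metrics
  n_deg <- 0L
  for (e in epochs$epochs) {
    idx <- trim_indices(ncol(e), trim)
    az <- lapply(seq_len(nc), function(c) analytic_signal(e[c, ])[idx])
    ph <- lapply(az, Arg)
    for (a in seq_len(nc - 1L)) {
      for (b in (a + 1L):nc) {
        for (m in metrics) {
          v <- switch(m,
                      plv = plv(ph[[a]], ph[[b]]),
                      pli = pli(ph[[a]], ph[[b]]),
                      wpli = wpli(az[[a]], az[[b]]))
          if (isTRUE(attr(v, "degenerate"))) n_deg <- n_deg + 1L
          acc[[m]][a, b] <- acc[[m]][a, b] + as.numeric(v)
        }
      }
    }
  }
  out <- lapply(metrics, function(m) {
    pairs <- acc[[m]] / length(epochs$epochs)
    pairs <- pairs + t(pairs)
    diag(pairs) <- NA_real_
    dimnames(pairs) <- list(epochs$channel_labels, epochs$channel_labels)
    list(value = mean(pairs[upper.tri(pairs)]), pairs = pairs, metric = m,
         band = if (!is.null(epochs$band)) epochs$band$name else
           NA_character_,
         n_epochs_used = length(epochs$epochs), n_degenerate = n_deg)
  })
  names(out) <- metrics
  out
}

#' Default preprocessing settings for feature extraction
#'
#' @return Named list of the preprocessing/connectivity defaults: target
#'   sampling rate 500 Hz, 2-s epochs, +/-200 uV amplitude and 0.1 uV
#'   flatline artifact thresholds, 10 percent edge trim, per-epoch Hilbert
#'   scope and 4th-order Butterworth filtering.
#' @export
preprocessing_defaults <- function() {
  list(target_fs = 500, epoch_length_s = 2, amplitude_threshold_uv = 200,
       flatline_eps = 0.1, trim = 0.1, hilbert_scope = "epoch",
       filter_order = 4L)
}

#' Extract the 18 global synchronization features of one recording
#'
#' Runs the full preprocessing chain (resample to the target rate, bipolar
#' derivation, 2-s epoching, artifact screen, per-band zero-phase filter)
#' and computes the global PLV, PLI and wPLI in each of the six bands.
#'
#' With `config$hilbert_scope = "epoch"` (default) metrics are computed
#' per 2-s epoch and averaged (favouring stationarity); with
#' `"recording"` the whole artifact-screened series is treated as a single
#' epoch (whole-series Hilbert transform).
#'
#' @param recording an [eeg_recording()].
#' @param bands named list of [band_definition()]s (default all six).
#' @param montage two-column electrode-pair matrix, or `NULL` to keep the
#'   recording's own channels (useful for low-channel synthetic data).
#' @param config preprocessing settings, see [preprocessing_defaults()];
#'   supplied entries override the defaults.
#' @return Named numeric vector of length `3 * length(bands)` (18 for the
#'   default bands), names `<metric>_<band>`, all values in \[0, 1\].
#'   Attribute `n_epochs_used` records how many clean epochs entered the
#'   metrics.
#' @export
extract_sync_features <- function(recording, bands = eeg_bands(),
                                  montage = default_montage(),
                                  config = list()) {
  cfg <- utils::modifyList(preprocessing_defaults(), config)
  rec <- recording
  if (rec$fs != cfg$target_fs) rec <- resample_recording(rec, cfg$target_fs)
  if (!is.null(montage)) rec <- to_bipolar(rec, montage)
  epochs <- segment_epochs(rec, cfg$epoch_length_s)
  epochs <- reject_artifacts(epochs, cfg$amplitude_threshold_uv,
                             cfg$flatline_eps)
  if (identical(cfg$hilbert_scope, "recording")) {
    # stitch the kept epochs back into a single segment
    whole <- do.call(cbind, epochs$epochs)
    epochs <- epoch_set(list(whole), epochs$fs,
                        ncol(whole) / epochs$fs, epochs$channel_labels,
                        epochs$montage_pairs)
  }
  metrics <- c("plv", "pli", "wpli")
  per_band <- lapply(names(bands), function(bn) {
    filtered <- bandpass_epochs(epochs, bands[[bn]],
                                order = cfg$filter_order)
    vapply(all_metrics(filtered, metrics, trim = cfg$trim),
           `[[`, numeric(1), "value")
  })
  names(per_band) <- names(bands)
  out <- numeric(0)
  for (m in metrics) {
    for (bn in names(bands)) {
      v <- per_band[[bn]][[m]]
      names(v) <- paste0(m, "_", bn)
      out <- c(out, v)
    }
  }
  attr(out, "n_epochs_used") <- length(epochs$epochs)
  attr(out, "config") <- cfg
  out
}

#' Extract synchronization features for a whole cohort
#'
#' @param cohort a `synthetic_cohort` (or any list of elements carrying a
#'   `recording`).
#' @param ... passed to [extract_sync_features()].
#' @return data.frame: `subject_id` plus one named column per feature.
#' @export
cohort_sync_features <- function(cohort, ...) {
  rows <- lapply(cohort, function(s) {
    f <- extract_sync_features(s$recording, ...)
    cbind(data.frame(subject_id = s$recording$subject_id,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(f)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
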