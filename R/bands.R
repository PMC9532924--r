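#' Standard EEG frequency bands
#'
#' The six clinical EEG bands used throughout the package: delta (1-4 Hz),
#' theta (4-8 Hz), alpha (8-13 Hz), low beta (13-20 Hz), high beta
#' (20-29 Hz) and the combined beta band (13-29 Hz). Band edges are in Hz.
#'
#' @param names optional character vector restricting the returned bands.
#' @return A named list of band definitions, each a list with elements
#'   `name`, `low` and `high`.
#' @export
#' @examples
#' eeg_bands()[["alpha"]]
eeg_bands <- function(names = NULL) {
  bands <- list(
    delta     = band_definition("delta", 1, 4),
    theta     = band_definition("theta", 4, 8),
    alpha     = band_definition("alpha", 8, 13),
    beta      = band_definition("beta", 13, 29),
    low_beta  = band_definition("low_beta", 13, 20),
    high_beta = band_definition("high_beta", 20, 29)
  )
  if (is.null(names)) return(bands)
  missing <- setdiff(names, names(bands))
  if (length(missing) > 0) {
    stop("unknown band(s): ", paste(missing, collapse = ", "))
  }
  bands[names]
}

#' Define a frequency band
#'
#' @param name band label.
#' @param low,high band edges in Hz, `0 < low < high`.
#' @return A `band_definition` list.
#' @export
band_definition <- function(name, low, high) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!(is.numeric(low) && is.numeric(high) && low > 0 && high > low)) {
    stop("band edges must satisfy 0 < low < high")
  }
  structure(list(name = name, low = low, high = high),
            class = "band_definition")
}

#' @export
print.band_definition <- function(x, ...) {
  cat(sprintf("<band> %s: %g-%g Hz\n", x$name, x$low, x$high))
  invisible(x)
}

#' The 19 scalp electrodes of the 10-20 system used by the pipeline
#'
#' @return Character vector of electrode labels in the conventional order.
#' @export
electrodes_1020 <- function() {
  c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2",
    "T3", "T4", "T5", "T6", "Fz", "Cz", "Pz", "F7", "F8")
}

#' Default longitudinal bipolar montage ("double banana")
#'
#' Eighteen anterior-to-posterior electrode pairs over the 19 standard
#' 10-20 electrodes: two temporal chains, two parasagittal chains and the
#' midline chain.
#'
#' @return A two-column character matrix; each row is one derived channel
#'   (first minus second electrode).
#' @export
default_montage <- function() {
  pairs <- rbind(
    c("Fp1", "F7"), c("F7", "T3"), c("T3", "T5"), c("T5", "O1"),
    c("Fp2", "F8"), c("F8", "T4"), c("T4", "T6"), c("T6", "O2"),
    c("Fp1", "F3"), c("F3", "C3"), c("C3", "P3"), c("P3", "O1"),
    c("Fp2", "F4"), c("F4", "C4"), c("C4", "P4"), c("P4", "O2"),
    c("Fz", "Cz"), c("Cz", "Pz")
  )
  colnames(pairs) <- c("anode", "cathode")
  pairs
}

# centre frequency of a band, used by the oscillator generator
band_centre <- function(band) (band$low + band$high) / 2
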