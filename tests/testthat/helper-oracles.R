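# Independent brute-force oracles: naive per-sample loops, no shared code
# with the package implementations.

bf_plv <- function(pa, pb) {
  sc <- 0; ss <- 0
  for (t in seq_along(pa)) {
    d <- pa[t] - pb[t]
    sc <- sc + cos(d)
    ss <- ss + sin(d)
  }
  sqrt(sc^2 + ss^2) / length(pa)
}

bf_pli <- function(pa, pb) {
  s <- 0
  for (t in seq_along(pa)) {
    d <- atan2(sin(pa[t] - pb[t]), cos(pa[t] - pb[t]))
    s <- s + if (d > 0 && d < pi) 1 else if (d < 0) -1 else 0
  }
  abs(s) / length(pa)
}

bf_wpli <- function(za, zb) {
  num <- 0; den <- 0
  for (t in seq_along(za)) {
    im <- Im(za[t]) * Re(zb[t]) - Re(za[t]) * Im(zb[t])
    num <- num + im
    den <- den + abs(im)
  }
  if (den == 0) 0 else abs(num) / den
}

# hand-applied Benjamini-Hochberg step-up rule
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# two equal-length sinusoid channels with a fixed phase offset, as an
# eeg_recording
sinusoid_recording <- function(freq = 10, lag = pi / 4, duration_s = 10,
                               fs = 500, amplitude = 50) {
  t <- (seq_len(duration_s * fs) - 1) / fs
  data <- rbind(amplitude * cos(2 * pi * freq * t),
                amplitude * cos(2 * pi * freq * t - lag))
  eeg_recording(data, fs, c("C3", "C4"), "sine")
}

# random phase pair / analytic pair fixtures
rand_phases <- function(n) stats::runif(n, -pi, pi)
rand_analytic <- function(n) {
  complex(real = stats::rnorm(n), imaginary = stats::rnorm(n))
}

# small fast cohort used by the Monte-Carlo suites: 70 subjects, 2
# channels, 8 s at 200 Hz
fast_cohort_spec <- function(seed, c_resp = 0.8, c_nr = 0.4) {
  cohort_spec(
    n_subjects = 70, responder_fraction = 37 / 70,
    responder_coupling = coupling_spec("high_beta", c_resp,
                                       mixing_coefficient = 0.1),
    nonresponder_coupling = coupling_spec("high_beta", c_nr,
                                          mixing_coefficient = 0.1),
    duration_s = 8, fs = 200, n_channels = 2, seed = seed)
}

bands_tested <- function() {
  eeg_bands(c("delta", "theta", "alpha", "low_beta", "high_beta"))
}

fast_features <- function(cohort, bands = bands_tested()) {
  cohort_sync_features(cohort, bands = bands, montage = NULL,
                       config = list(target_fs = 200))
}

cohort_labels <- function(cohort) {
  vapply(cohort, `[[`, character(1), "true_label")
}
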