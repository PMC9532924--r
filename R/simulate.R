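#' Specify pairwise phase coupling for the synthetic EEG generator
#'
#' The generator plants synchronization by driving all channels from one
#' common narrowband phase process and adding independent per-channel
#' von Mises phase jitter. `coupling_strength` maps monotonically to the
#' jitter concentration via `kappa = tan(coupling_strength * pi / 2)`, so
#' 0 gives independent phases (uniform jitter) and 1 rigid locking (no
#' jitter). `mixing_coefficient` adds instantaneous (zero-lag, real-valued)
#' symmetric channel mixing emulating volume conduction.
#'
#' @param band_name band carrying the planted oscillation; one of
#'   `"delta"`, `"theta"`, `"alpha"`, `"low_beta"`, `"high_beta"` (the
#'   combined beta band is a union of the two beta sub-bands and cannot
#'   carry its own oscillator).
#' @param coupling_strength unitless in \[0, 1\].
#' @param phase_lag per-channel phase offset in radians in (-pi, pi];
#'   channel c is offset by `(c - 1) * phase_lag`.
#' @param mixing_coefficient unitless in \[0, 1\]; 0 disables mixing.
#' @param noise_sd standard deviation of additive broadband Gaussian noise,
#'   relative to the oscillation amplitude of 1.
#' @return A `coupling_spec` list.
#' @export
coupling_spec <- function(band_name = "high_beta", coupling_strength = 0.5,
                          phase_lag = pi / 4, mixing_coefficient = 0,
                          noise_sd = 1) {
  allowed <- c("delta", "theta", "alpha", "low_beta", "high_beta")
  if (!band_name %in% allowed) {
    stop("band_name must be one of: ", paste(allowed, collapse = ", "))
  }
  stopifnot(coupling_strength >= 0, coupling_strength <= 1,
            mixing_coefficient >= 0, mixing_coefficient <= 1,
            noise_sd >= 0,
            phase_lag > -pi, phase_lag <= pi)
  structure(list(band_name = band_name,
                 coupling_strength = coupling_strength,
                 phase_lag = phase_lag,
                 mixing_coefficient = mixing_coefficient,
                 noise_sd = noise_sd),
            class = "coupling_spec")
}

# deterministic per-subject sub-seed: one base seed fans out to independent
# substreams so each subject is reproducible on its own
derive_seed <- function(seed, counter) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(counter) * 16807
  as.integer(s %% 2147483647) + 1L
}

# Best & Fisher (1979) rejection sampler for the von Mises distribution,
# mean 0, concentration kappa. kappa = 0 -> uniform, kappa = Inf -> point
# mass at 0.
rvonmises <- function(n, kappa) {
  if (n == 0L) return(numeric(0))
  if (!is.finite(kappa) || kappa > 1e12) return(rep(0, n))
  if (kappa < 1e-10) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  filled <- 0L
  while (filled < n) {
    m <- n - filled
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    if (any(ok)) {
      th <- sign(u3[ok] - 0.5) * acos(pmin(1, pmax(-1, f[ok])))
      k <- length(th)
      out[(filled + 1L):(filled + k)] <- th
      filled <- filled + k
    }
  }
  out
}

coupling_to_kappa <- function(coupling_strength) {
  if (coupling_strength >= 1) return(Inf)
  tan(coupling_strength * pi / 2)
}

#' Generate a multichannel recording with controlled phase coupling
#'
#' All channels share a common narrowband oscillator (centre frequency =
#' the middle of `spec$band_name`, with slow phase diffusion so the line
#' has finite width); channel c receives a fixed offset
#' `(c - 1) * spec$phase_lag` plus independent per-sample von Mises jitter
#' whose concentration grows with `spec$coupling_strength`. Independent
#' broadband Gaussian noise at `spec$noise_sd` is added, and if
#' `spec$mixing_coefficient > 0` channels are mixed by the symmetric
#' zero-lag matrix `(1 - m) I + (m / n) J` (each channel pulled toward the
#' common average), emulating volume conduction. Deterministic given
#' `seed`.
#'
#' @param n_channels number of channels, 2..19; labels are taken from
#'   [electrodes_1020()].
#' @param duration_s recording length in seconds (at least one 2-s epoch).
#' @param fs sampling rate in Hz; must exceed twice the band's upper edge.
#' @param spec a [coupling_spec()].
#' @param seed integer seed.
#' @param amplitude_uv oscillation amplitude in microvolts (the
#'   relative amplitude 1); 20 uV keeps clean bipolar derivations well
#'   inside the default 200 uV artifact threshold.
#' @param phase_diffusion standard deviation of the common oscillator's
#'   phase random walk, rad per sqrt(second); gives the planted line a
#'   realistic finite width without breaking inter-channel locking.
#' @return An [eeg_recording()].
#' @export
generate_coupled_recording <- function(n_channels, duration_s, fs, spec,
                                       seed = 1L, amplitude_uv = 20,
                                       phase_diffusion = 1) {
  stopifnot(inherits(spec, "coupling_spec"))
  if (n_channels < 2) stop("need at least 2 channels")
  labels <- electrodes_1020()
  if (n_channels > length(labels)) {
    stop("n_channels > 19 exceeds the default 10-20 label set")
  }
  band <- eeg_bands()[[spec$band_name]]
  if (fs <= 2 * band$high) {
    stop(sprintf("fs = %g Hz is below Nyquist for band %s (upper edge %g Hz)",
                 fs, band$name, band$high))
  }
  ns <- round(duration_s * fs)
  if (ns < 2 * fs) stop("duration must cover at least one 2-s epoch")

  set.seed(as.integer(seed %% 2147483647))
  fc <- band_centre(band)
  # common oscillator: linear phase + diffusion (shared by all channels,
  # so it never degrades inter-channel locking)
  phi0 <- 2 * pi * fc * (seq_len(ns) - 1) / fs +
    cumsum(stats::rnorm(ns, 0, phase_diffusion / sqrt(fs)))
  kappa <- coupling_to_kappa(spec$coupling_strength)
  x <- matrix(0, n_channels, ns)
  for (c in seq_len(n_channels)) {
    jitter <- rvonmises(ns, kappa)
    x[c, ] <- cos(phi0 + (c - 1) * spec$phase_lag + jitter)
  }
  if (spec$noise_sd > 0) {
    x <- x + matrix(stats::rnorm(n_channels * ns, 0, spec$noise_sd),
                    n_channels, ns)
  }
  m <- spec$mixing_coefficient
  if (m > 0) {
    mix <- diag(1 - m, n_channels) + m / n_channels
    x <- mix %*% x
  }
  eeg_recording(x * amplitude_uv, fs, labels[seq_len(n_channels)],
                subject_id = sprintf("sim%06d", as.integer(seed %% 1e6)))
}

#' Default clinical covariate distributions for the synthetic cohort
#'
#' Pooled means, standard deviations and category frequencies of the
#' baseline clinical variables of a 70-patient pediatric drug-resistant
#' epilepsy cohort (responders and non-responders pooled, since no
#' clinical variable separated the groups at baseline). Seizure frequency
#' is log-normal (heavily right-skewed in such cohorts); age at
#' implantation is derived as onset age + epilepsy duration so the three
#' age variables stay mutually consistent.
#'
#' @return A named list of distribution parameters consumed by
#'   [generate_cohort()].
#' @export
default_clinical_distributions <- function() {
  list(
    # continuous: mean, sd, lower truncation
    seizure_frequency = list(meanlog = 6.0, sdlog = 1.05, min = 1),
    bmi = list(mean = 16.7, sd = 3.2, min = 10),
    diastolic_pressure = list(mean = 59.8, sd = 6.2, min = 35),
    pulse_pressure = list(mean = 41.2, sd = 7.4, min = 15),
    age_onset = list(mean = 2.2, sd = 2.7, min = 0),
    epilepsy_duration = list(mean = 3.3, sd = 1.9, min = 0.5),
    n_asm_baseline = list(mean = 3.0, sd = 1.0, min = 0, max = 6),
    n_asm_historical = list(mean = 5.5, sd = 2.0, min = 0, max = 12),
    # binary probabilities
    p_male = 44 / 70,
    p_prior_surgery = 9 / 70,
    p_benzodiazepine = 34 / 70,
    # exclusive categories
    etiology = c(structural = 39 / 70, genetic = 3 / 70,
                 autoimmune = 1 / 70, unknown = 27 / 70),
    syndrome = c(infantile_spasms = 15 / 70, lgs = 5 / 70, eoee = 8 / 70,
                 unclassified = 42 / 70),
    mri = c(local = 7 / 70, multifocal = 36 / 70, negative = 27 / 70),
    # non-exclusive seizure types (multi-hot)
    p_seizure_types = c(generalized = 22 / 70, focal = 33 / 70,
                        spasms = 39 / 70, multiple = 32 / 70)
  )
}

#' Specify a synthetic cohort
#'
#' @param n_subjects cohort size (>= 2).
#' @param responder_fraction proportion of responders, strictly between 0
#'   and 1.
#' @param responder_coupling,nonresponder_coupling [coupling_spec()]s
#'   applied to the two groups; the defaults plant an elevated high-beta
#'   coupling in responders (0.8 vs 0.4) with no clinical effect.
#' @param clinical_distributions see [default_clinical_distributions()].
#' @param duration_s seconds of clean awake EEG per subject.
#' @param fs sampling rate in Hz.
#' @param n_channels electrodes per subject (10-20 labels).
#' @param seed integer master seed; each subject draws from its own
#'   derived substream.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 70,
                        responder_fraction = 37 / 70,
                        responder_coupling = coupling_spec(
                          "high_beta", coupling_strength = 0.8,
                          mixing_coefficient = 0.1),
                        nonresponder_coupling = coupling_spec(
                          "high_beta", coupling_strength = 0.4,
                          mixing_coefficient = 0.1),
                        clinical_distributions =
                          default_clinical_distributions(),
                        duration_s = 60, fs = 500, n_channels = 19,
                        seed = 1L) {
  stopifnot(n_subjects >= 2,
            responder_fraction > 0, responder_fraction < 1,
            inherits(responder_coupling, "coupling_spec"),
            inherits(nonresponder_coupling, "coupling_spec"))
  if (duration_s * fs < 2 * fs) stop("duration_s must cover >= one 2-s epoch")
  structure(list(n_subjects = as.integer(n_subjects),
                 responder_fraction = responder_fraction,
                 responder_coupling = responder_coupling,
                 nonresponder_coupling = nonresponder_coupling,
                 clinical_distributions = clinical_distributions,
                 duration_s = duration_s, fs = fs,
                 n_channels = as.integer(n_channels),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

rnorm_trunc <- function(n, mean, sd, min = -Inf, max = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < min | x > max)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < min | x > max)
  }
  x
}

sample_category <- function(probs) {
  names(probs)[which(stats::runif(1) <= cumsum(probs / sum(probs)))[1]]
}

# one subject's clinical record (one-row data.frame); no planted group
# effect: both labels draw from the same distributions
sample_clinical <- function(dist, subject_id) {
  onset <- round(rnorm_trunc(1, dist$age_onset$mean, dist$age_onset$sd,
                             dist$age_onset$min), 1)
  dur <- round(rnorm_trunc(1, dist$epilepsy_duration$mean,
                           dist$epilepsy_duration$sd,
                           dist$epilepsy_duration$min), 1)
  st <- stats::runif(4) < dist$p_seizure_types
  if (!any(st)) st[2] <- TRUE  # every patient has at least one seizure type
  data.frame(
    subject_id = subject_id,
    gender = if (stats::runif(1) < dist$p_male) "male" else "female",
    bmi = round(rnorm_trunc(1, dist$bmi$mean, dist$bmi$sd, dist$bmi$min), 1),
    diastolic_pressure = round(rnorm_trunc(
      1, dist$diastolic_pressure$mean, dist$diastolic_pressure$sd,
      dist$diastolic_pressure$min)),
    pulse_pressure = round(rnorm_trunc(
      1, dist$pulse_pressure$mean, dist$pulse_pressure$sd,
      dist$pulse_pressure$min)),
    age_onset = onset,
    epilepsy_duration = dur,
    age_implantation = onset + dur,
    prior_surgery = stats::runif(1) < dist$p_prior_surgery,
    seizure_frequency = round(max(dist$seizure_frequency$min, stats::rlnorm(
      1, dist$seizure_frequency$meanlog, dist$seizure_frequency$sdlog)), 1),
    etiology = sample_category(dist$etiology),
    seizure_generalized = st[1], seizure_focal = st[2],
    seizure_spasms = st[3], seizure_multiple = st[4],
    syndrome = sample_category(dist$syndrome),
    mri = sample_category(dist$mri),
    n_asm_baseline = round(rnorm_trunc(
      1, dist$n_asm_baseline$mean, dist$n_asm_baseline$sd,
      dist$n_asm_baseline$min, dist$n_asm_baseline$max)),
    n_asm_historical = round(rnorm_trunc(
      1, dist$n_asm_historical$mean, dist$n_asm_historical$sd,
      dist$n_asm_historical$min, dist$n_asm_historical$max)),
    benzodiazepine = stats::runif(1) < dist$p_benzodiazepine,
    stringsAsFactors = FALSE
  )
}

# diary consistent with the planted label: responders draw a reduction
# >= 0.5 (with the R100/R80/R50 mix of the emulated cohort), non-responders
# a reduction < 0.5 (negative reductions allowed)
sample_diary <- function(baseline_freq, responder) {
  if (responder) {
    grp <- sample_category(c(r100 = 10 / 37, r80 = 18 / 37, r50 = 9 / 37))
    reduction <- switch(grp,
                        r100 = 1,
                        r80 = stats::runif(1, 0.8, 0.999),
                        r50 = stats::runif(1, 0.5, 0.799))
  } else {
    reduction <- stats::runif(1, -0.3, 0.499)
  }
  list(baseline_freq = baseline_freq,
       followup_freq = round(baseline_freq * (1 - reduction), 2))
}

#' Generate a full synthetic cohort with a planted responder effect
#'
#' Labels are drawn first (exactly `round(n * responder_fraction)`
#' responders, order shuffled), then each subject receives an EEG
#' recording with their group's coupling, clinical covariates from the
#' shared distributions (no planted clinical effect) and a seizure diary
#' consistent with the label. All randomness flows from `spec$seed`
#' through per-subject substreams, so any subject is bit-reproducible in
#' isolation.
#'
#' @param spec a [cohort_spec()].
#' @return A list of class `synthetic_cohort`: one element per subject with
#'   fields `recording`, `clinical` (one-row data.frame), `diary`
#'   (baseline/follow-up seizure frequencies) and `true_label`
#'   (`"R50"`/`"NR50"`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  n_resp <- round(n * spec$responder_fraction)
  if (n_resp < 1 || n_resp > n - 1) stop("responder_fraction too extreme")
  set.seed(spec$seed)
  responder <- sample(rep(c(TRUE, FALSE), c(n_resp, n - n_resp)))
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    sid <- sprintf("S%03d", i)
    sub_seed <- derive_seed(spec$seed, i)
    set.seed(sub_seed)
    clin <- sample_clinical(spec$clinical_distributions, sid)
    diary <- sample_diary(clin$seizure_frequency, responder[i])
    cspec <- if (responder[i]) spec$responder_coupling else
      spec$nonresponder_coupling
    rec <- generate_coupled_recording(spec$n_channels, spec$duration_s,
                                      spec$fs, cspec,
                                      seed = derive_seed(sub_seed, 1L))
    rec$subject_id <- sid
    subjects[[i]] <- list(recording = rec, clinical = clin, diary = diary,
                          true_label = if (responder[i]) "R50" else "NR50")
  }
  structure(subjects, class = "synthetic_cohort", seed = spec$seed)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  lab <- vapply(x, `[[`, character(1), "true_label")
  cat(sprintf("<synthetic_cohort> %d subjects (%d R50, %d NR50)\n",
              length(x), sum(lab == "R50"), sum(lab == "NR50")))
  invisible(x)
}

#' Bind a cohort's clinical records into one data frame
#' @param cohort a `synthetic_cohort`.
#' @return data.frame, one row per subject, with `true_label`,
#'   `baseline_freq` and `followup_freq` appended.
#' @export
cohort_clinical_table <- function(cohort) {
  out <- do.call(rbind, lapply(cohort, `[[`, "clinical"))
  out$baseline_freq <- vapply(cohort, function(s) s$diary$baseline_freq,
                              numeric(1))
  out$followup_freq <- vapply(cohort, function(s) s$diary$followup_freq,
                              numeric(1))
  out$true_label <- vapply(cohort, `[[`, character(1), "true_label")
  rownames(out) <- NULL
  out
}
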