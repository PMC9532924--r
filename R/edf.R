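# fixed-width ASCII header field
edf_field <- function(value, width) {
  s <- sprintf("%-*s", width, as.character(value))
  if (nchar(s) > width) s <- substr(s, 1L, width)
  s
}

#' Write a recording to an EDF file
#'
#' Minimal EDF (16-bit) writer: one data record per second, physical units
#' microvolts, symmetric per-channel physical range. The sampling rate must
#' be a positive integer; a trailing partial second is dropped with a
#' warning.
#'
#' @param recording an [eeg_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$fs
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(fs)
  x <- recording$data
  nrec <- ncol(x) %/% fs
  if (nrec < 1L) stop("recording shorter than one 1-s data record")
  if (nrec * fs != ncol(x)) {
    warning("dropping trailing partial second for EDF record alignment")
    x <- x[, seq_len(nrec * fs), drop = FALSE]
  }
  nsig <- nrow(x)
  phys_max <- apply(x, 1L, function(ch) max(abs(ch)))
  phys_max[phys_max == 0] <- 1
  phys_max <- signif(phys_max, 7)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_field("0", 8L),
    edf_field(recording$subject_id, 80L),
    edf_field("vnseeg synthetic", 80L),
    edf_field("01.01.00", 8L),
    edf_field("00.00.00", 8L),
    edf_field(256L * (nsig + 1L), 8L),
    edf_field("", 44L),
    edf_field(nrec, 8L),
    edf_field(1, 8L),
    edf_field(nsig, 4L)
  )
  sig_hdr <- paste0(
    paste(vapply(recording$channel_labels, edf_field, "", width = 16L),
          collapse = ""),
    paste(rep(edf_field("", 80L), nsig), collapse = ""),
    paste(rep(edf_field("uV", 8L), nsig), collapse = ""),
    paste(vapply(-phys_max, edf_field, "", width = 8L), collapse = ""),
    paste(vapply(phys_max, edf_field, "", width = 8L), collapse = ""),
    paste(rep(edf_field(-32767L, 8L), nsig), collapse = ""),
    paste(rep(edf_field(32767L, 8L), nsig), collapse = ""),
    paste(rep(edf_field("", 80L), nsig), collapse = ""),
    paste(rep(edf_field(fs, 8L), nsig), collapse = ""),
    paste(rep(edf_field("", 32L), nsig), collapse = "")
  )
  writeChar(paste0(hdr, sig_hdr), con, eos = NULL, useBytes = TRUE)
  dig <- round(sweep(x, 1L, phys_max, "/") * 32767)
  dig <- pmin(pmax(dig, -32767), 32767)
  for (r in seq_len(nrec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    block <- as.integer(t(dig[, cols, drop = FALSE]))
    writeBin(block, con, size = 2L, endian = "little")
  }
  invisible(path)
}

# default normalization of vendor-style channel labels: "EEG Fp1-Ref" -> "Fp1"
normalize_channel_label <- function(label) {
  l <- trimws(label)
  l <- sub("^EEG[ .]+", "", l, ignore.case = TRUE)
  sub("[-. ](Ref|REF|LE|AV|A1|A2)$", "", l)
}

#' Read an EDF file into a recording
#'
#' Minimal EDF/EDF+ reader for continuous 16-bit recordings. Labels are
#' normalized (vendor prefixes such as `"EEG "` and reference suffixes
#' such as `"-Ref"` are stripped) and an optional explicit `label_map`
#' (named character vector, `raw = clean`) is applied afterwards. Channels
#' with differing sampling rates are resampled to the maximum rate with a
#' warning.
#'
#' @param path EDF file path.
#' @param label_map optional named character vector mapping raw labels to
#'   clean ones.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path, label_map = NULL) {
  if (!file.exists(path) || file.size(path) < 256) {
    stop("not a readable EDF file: ", path)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) {
    trimws(readChar(con, width, useBytes = TRUE))
  }
  rd(8L)                       # version
  patient <- rd(80L)
  rd(80L); rd(8L); rd(8L)      # recording id, date, time
  rd(8L)                       # header bytes
  rd(44L)
  nrec <- as.integer(rd(8L))
  rec_dur <- as.numeric(rd(8L))
  nsig <- as.integer(rd(4L))
  if (is.na(nsig) || nsig < 1L || is.na(nrec) || nrec < 1L) {
    stop("corrupt EDF header in ", path)
  }
  labels <- vapply(seq_len(nsig), function(i) rd(16L), "")
  for (i in seq_len(nsig)) rd(80L)                     # transducer
  for (i in seq_len(nsig)) rd(8L)                      # dimension
  phys_min <- vapply(seq_len(nsig), function(i) as.numeric(rd(8L)), 0)
  phys_max <- vapply(seq_len(nsig), function(i) as.numeric(rd(8L)), 0)
  dig_min <- vapply(seq_len(nsig), function(i) as.numeric(rd(8L)), 0)
  dig_max <- vapply(seq_len(nsig), function(i) as.numeric(rd(8L)), 0)
  for (i in seq_len(nsig)) rd(80L)                     # prefilter
  spr <- vapply(seq_len(nsig), function(i) as.integer(rd(8L)), 0L)
  for (i in seq_len(nsig)) rd(32L)

  data <- lapply(seq_len(nsig), function(i) numeric(nrec * spr[i]))
  for (r in seq_len(nrec)) {
    for (i in seq_len(nsig)) {
      raw <- readBin(con, integer(), n = spr[i], size = 2L,
                     endian = "little")
      gain <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
      data[[i]][((r - 1L) * spr[i] + 1L):(r * spr[i])] <-
        (raw - dig_min[i]) * gain + phys_min[i]
    }
  }
  fs_per <- spr / rec_dur
  fs <- max(fs_per)
  if (any(fs_per != fs)) {
    warning("channels sampled at different rates; resampling to ",
            fs, " Hz")
    for (i in which(fs_per != fs)) {
      a <- round(fs * 1000); b <- round(fs_per[i] * 1000)
      g <- gcd_int(a, b)
      data[[i]] <- resample_signal(data[[i]], a / g, b / g)
    }
  }
  n <- min(lengths(data))
  x <- do.call(rbind, lapply(data, `[`, seq_len(n)))
  labels <- vapply(labels, normalize_channel_label, "", USE.NAMES = FALSE)
  if (!is.null(label_map)) {
    hit <- labels %in% names(label_map)
    labels[hit] <- unname(label_map[labels[hit]])
  }
  if (!any(labels %in% c(electrodes_1020(),
                         paste0(default_montage()[, 1], "-",
                                default_montage()[, 2])))) {
    stop("no recognizable 10-20 channel labels in ", path)
  }
  eeg_recording(x, fs, labels,
                subject_id = if (nzchar(patient)) patient else "unknown")
}

#' Write a synthetic cohort to disk (EDF files + manifest)
#'
#' One EDF per subject plus a tab-delimited manifest with the clinical
#' fields, diary frequencies, the planted label and each EDF path.
#'
#' @param cohort a `synthetic_cohort`.
#' @param out_dir output directory (created if needed).
#' @return Path of the manifest file, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  edf_dir <- file.path(out_dir, "edf")
  dir.create(edf_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- cohort_clinical_table(cohort)
  # paths are stored relative to the manifest so cohort folders are
  # relocatable
  manifest$edf_path <- vapply(cohort, function(s) {
    rel <- file.path("edf", paste0(s$recording$subject_id, ".edf"))
    write_edf(s$recording, file.path(out_dir, rel))
    rel
  }, "")
  path <- file.path(out_dir, "manifest.tsv")
  utils::write.table(manifest, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
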