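# Two-class synthetic EEG: coupled band-limited oscillators plus 1/f noise.
#
# Each channel is a mixture of (a) cohort-shared band oscillators received
# with a fixed per-channel phase lag -- the source of inter-channel phase
# synchrony that PLI detects -- and (b) channel-private oscillators and
# broadband noise. The shared fraction is the coupling strength; the
# broadband-noise fraction (complexity scale) raises Sample Entropy.
# Controls are generated with stronger coupling than stroke subjects and
# higher complexity, the direction of the clinical effect the pipeline
# exploits.

#' Configuration for the synthetic EEG generator
#'
#' Defaults emulate the study conditions the pipeline targets: 19-channel
#' 10-20 EEG at 256 Hz, roughly five minutes per subject, a cohort of 20
#' stroke-like and 19 control-like subjects, and band-limited 1-35 Hz
#' content spanning the delta/theta/alpha/beta bands.
#'
#' @param n_channels Number of channels (default 19).
#' @param fs Sampling rate in Hz (default 256).
#' @param duration_s Seconds of signal per subject (default 300).
#' @param n_subjects_per_class Named count `c(stroke=, control=)` or a single
#'   count applied to both classes.
#' @param coupling_strength Named vector `c(control=, stroke=)` in `[0,1]`:
#'   fraction of each band oscillator's power shared cohort-wide. Controls
#'   couple more strongly than stroke subjects by default (0.6 vs 0.3).
#' @param noise_sd Standard deviation of additive broadband white noise,
#'   relative to unit oscillator power (default 0.2).
#' @param complexity_scale Named vector `c(control=, stroke=)` > 0 scaling
#'   the 1/f broadband component; larger values raise Sample Entropy.
#' @param band_freqs Centre frequencies (Hz) of the delta/theta/alpha/beta
#'   oscillators.
#' @param band_amps Relative amplitudes of the band oscillators.
#' @param amp_uv Overall output scale in microvolts.
#' @param pair Optional channel index pair `c(i, j)` given an extra private
#'   oscillator shared only between those two channels.
#' @param pair_coupling Named vector `c(control=, stroke=)`: power fraction
#'   of the pair-private oscillator, per class. Lets tests construct cohorts
#'   where exactly one channel pair is differentially coupled.
#' @param seed Integer master seed; every subject's signal is a pure
#'   function of (seed, class, subject index).
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_channels = 19L, fs = 256, duration_s = 300,
                         n_subjects_per_class = c(stroke = 20L, control = 19L),
                         coupling_strength = c(control = 0.6, stroke = 0.3),
                         noise_sd = 0.2,
                         complexity_scale = c(control = 1.0, stroke = 0.6),
                         band_freqs = c(delta = 2.5, theta = 6, alpha = 10,
                                        beta = 20),
                         band_amps = c(delta = 1.0, theta = 0.8, alpha = 1.2,
                                       beta = 0.6),
                         amp_uv = 30,
                         pair = NULL, pair_coupling = c(control = 0, stroke = 0),
                         seed = 1L) {
  if (n_channels <= 0 || duration_s <= 0 || fs <= 0)
    stop("n_channels, fs and duration_s must be positive")
  if (length(n_subjects_per_class) == 1L)
    n_subjects_per_class <- c(stroke = unname(n_subjects_per_class),
                              control = unname(n_subjects_per_class))
  stopifnot(all(coupling_strength >= 0), all(coupling_strength <= 1),
            noise_sd >= 0, all(complexity_scale > 0),
            length(band_freqs) == length(band_amps))
  if (!is.null(pair)) {
    stopifnot(length(pair) == 2L, all(pair >= 1), all(pair <= n_channels),
              pair[1] != pair[2])
    if (any(coupling_strength + max(pair_coupling) > 1))
      stop("coupling_strength + pair_coupling must not exceed 1")
  }
  structure(list(
    n_channels = as.integer(n_channels), fs = fs, duration_s = duration_s,
    n_subjects_per_class = n_subjects_per_class,
    coupling_strength = coupling_strength, noise_sd = noise_sd,
    complexity_scale = complexity_scale, band_freqs = band_freqs,
    band_amps = band_amps, amp_uv = amp_uv,
    pair = pair, pair_coupling = pair_coupling,
    seed = as.integer(seed)
  ), class = "synth_config")
}

.class_name <- function(label) if (label == 1L) "stroke" else "control"

.subject_seed <- function(config, class_label, subject_index) {
  as.integer((as.numeric(config$seed) * 7919 + class_label * 104729 +
                subject_index * 131) %% 2147483629)
}

# 1/f-shaped Gaussian noise of length n (unit variance), via spectral shaping
.pink_noise <- function(n) {
  w <- rnorm(n)
  W <- fft(w)
  f <- c(1, seq_len(n - 1))            # avoid division by zero at DC
  f <- pmin(f, n - f + 1)              # two-sided frequency index
  W <- W / sqrt(f)
  x <- Re(fft(W, inverse = TRUE)) / n
  x / sd(x)
}

# slowly drifting oscillator phase: linear trend + random-walk jitter
.osc_phase <- function(freq, n, fs, drift_sd = 0.03) {
  2 * pi * freq * seq_len(n) / fs + cumsum(rnorm(n, 0, drift_sd)) +
    runif(1, 0, 2 * pi)
}

#' Generate one synthetic EEG subject
#'
#' Deterministic given `(config$seed, class_label, subject_index)`: the same
#' call always returns bit-identical data.
#'
#' @param config A [synth_config()].
#' @param class_label 1 = stroke-like, 0 = control-like.
#' @param subject_index Index within the class (drives the per-subject seed).
#' @return An [eeg_recording()] with band-limited 1-35 Hz content.
#' @export
generate_subject <- function(config, class_label, subject_index = 1L) {
  stopifnot(inherits(config, "synth_config"), class_label %in% c(0L, 1L))
  cls <- .class_name(class_label)
  C <- config$n_channels
  n <- round(config$fs * config$duration_s)
  if (n < 1) stop("non-positive duration")
  coupling <- unname(config$coupling_strength[cls])
  cx <- unname(config$complexity_scale[cls])
  pair_c <- if (is.null(config$pair)) 0 else unname(config$pair_coupling[cls])
  lags <- montage_lags(C)
  B <- length(config$band_freqs)

  with_local_seed(.subject_seed(config, class_label, subject_index), {
    # cohort-shared oscillator phases, one per band, received by every
    # channel with its fixed montage lag
    common <- lapply(seq_len(B), function(b)
      .osc_phase(config$band_freqs[b], n, config$fs))
    priv_pair <- if (pair_c > 0)
      .osc_phase(config$band_freqs[which.max(config$band_amps)], n, config$fs)
    dat <- matrix(0, C, n)
    for (ch in seq_len(C)) {
      osc_shared <- 0
      osc_priv <- 0
      for (b in seq_len(B)) {
        a <- config$band_amps[b]
        osc_shared <- osc_shared + a * cos(common[[b]] + lags[ch])
        osc_priv <- osc_priv +
          a * cos(.osc_phase(config$band_freqs[b], n, config$fs))
      }
      p <- if (!is.null(config$pair) && ch %in% config$pair) pair_c else 0
      x <- sqrt(coupling) * osc_shared +
        sqrt(max(0, 1 - coupling - p)) * osc_priv
      if (p > 0) x <- x + sqrt(p) *
          sum(config$band_amps) / sqrt(B) * cos(priv_pair + lags[ch])
      x <- x + cx * .pink_noise(n) + config$noise_sd * rnorm(n)
      dat[ch, ] <- x
    }
    dat <- dat * config$amp_uv
    rec <- eeg_recording(dat, fs = config$fs,
                         channel_names = if (C == 19L) montage_channels()
                         else paste0("ch", seq_len(C)),
                         subject_id = sprintf("%s%02d",
                                              if (class_label == 1L) "IS" else "NC",
                                              subject_index),
                         label = class_label)
    bandpass_filter(rec, 1, 35)
  })
}

#' Generate a full two-class cohort
#'
#' @param config A [synth_config()].
#' @return List of [eeg_recording()] objects, stroke subjects first.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  ns <- config$n_subjects_per_class
  c(lapply(seq_len(ns[["stroke"]]), function(i)
      generate_subject(config, 1L, i)),
    lapply(seq_len(ns[["control"]]), function(i)
      generate_subject(config, 0L, i)))
}

#' Theoretical amplitude bound of the generator output
#'
#' Oscillators are bounded by the summed band amplitudes; Gaussian noise is
#' bounded here at ten standard deviations, an event of negligible
#' probability at the sample counts the generator produces. Includes a 50%
#' margin for zero-phase filter transients.
#'
#' @param config A [synth_config()].
#' @return Bound in microvolts.
#' @export
amplitude_bound <- function(config) {
  osc <- 2 * sum(config$band_amps)           # shared + private + pair terms
  noise <- 10 * (config$noise_sd + max(config$complexity_scale))
  1.5 * config$amp_uv * (osc + noise)
}

#' Write a cohort as EDF files plus a labels table
#'
#' One EDF per subject and a `labels.csv` with columns `subject_id,label`.
#'
#' @param cohort List of recordings from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Path of the labels CSV, invisibly.
#' @export
write_cohort_edf <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- vapply(cohort, function(r) r$subject_id, "")
  labels <- vapply(cohort, function(r) as.integer(r$label), 0L)
  for (rec in cohort)
    edf_write(rec, file.path(dir, paste0(rec$subject_id, ".edf")))
  csv <- file.path(dir, "labels.csv")
  write.csv(data.frame(subject_id = ids, label = labels),
            csv, row.names = FALSE)
  invisible(csv)
}

#' Read a cohort written by [write_cohort_edf()]
#'
#' @param dir Directory containing per-subject EDF files and `labels.csv`.
#' @return List of [eeg_recording()] objects.
#' @export
read_cohort_edf <- function(dir) {
  tab <- read.csv(file.path(dir, "labels.csv"))
  lapply(seq_len(nrow(tab)), function(i) {
    rec <- edf_read(file.path(dir, paste0(tab$subject_id[i], ".edf")),
                    label = as.integer(tab$label[i]))
    rec$subject_id <- tab$subject_id[i]
    rec
  })
}
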