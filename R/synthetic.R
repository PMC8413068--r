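# Synthetic two-class multichannel generator. Emulates the layout of the
# public mental-arithmetic recordings (21 named channels, a long baseline
# trial and a shorter task trial, one fixed sampling rate, G/B subject
# labels) with the statistical structure the pipeline assumes: each EEG
# channel is a sum of amplitude-modulated narrowband oscillations plus
# white noise, and the two classes differ only in the variance of the
# band-amplitude modulation.

.default_bands <- function() {
  # classical EEG rhythm centers; amplitudes fall off with frequency
  data.frame(center    = c(4, 8, 12, 20, 30),     # Hz
             mod_rate  = c(0.4, 0.5, 0.7, 1.0, 1.3),  # Hz, envelope speed
             amplitude = c(20, 15, 10, 6, 4))     # uV
}

# Smooth zero-mean unit-sd noise: circular moving average of white noise,
# window set by the modulation rate.
.smooth_noise <- function(n, fs, rate) {
  w <- max(3L, round(fs / rate / 2))
  e <- stats::filter(stats::rnorm(n + 2L * w), rep(1 / w, w),
                     circular = TRUE)[w + seq_len(n)]
  s <- stats::sd(e)
  if (!is.finite(s) || s < 1e-12) return(rep(0, n))
  as.numeric(e) / s
}

.ecg_trace <- function(n, fs, rate = 1.1) {
  t <- seq_len(n) / fs
  x <- numeric(n)
  beat <- 0
  while (beat < t[n]) {
    # R-peak-like Gaussian pulse, ~40 ms wide, with slight rate jitter
    x <- x + exp(-((t - beat)^2) / (2 * 0.02^2))
    beat <- beat + 1 / rate + stats::rnorm(1, 0, 0.02)
  }
  x + 0.02 * stats::rnorm(n)
}

#' Generate synthetic two-class recordings
#'
#' Produces per-subject baseline and task [Recording-class] objects plus
#' a label table. Each EEG channel is
#' `sum_b A_b (1 + m_b(t)) cos(2 pi f_b t + phi) + noise`, where `m_b(t)`
#' is smooth zero-mean noise whose standard deviation is `modSd` for
#' class G and `modSd * sqrt(1 + effectSize)` for class B — so the
#' classes differ exactly in the mode-wise amplitude variability that the
#' Poincare descriptors measure, not in mean amplitude. The ECG channel
#' is a ~1.1 Hz spike train, identical in law for both classes. Fully
#' deterministic under `seed`.
#'
#' @param nGood,nBad subject counts per class (default 10 + 10).
#' @param fs sampling rate in Hz (default 128).
#' @param durationTask,durationBaseline trial lengths in seconds
#'   (defaults 60 and 180, the public layout).
#' @param channels montage (default [eegmatMontage()]); any label
#'   containing `ECG` gets the spike-train trace.
#' @param bands data.frame with columns `center` (Hz), `mod_rate` (Hz)
#'   and `amplitude`; band centers must stay below `fs / 2`.
#' @param effectSize nonnegative; 0 makes the classes identical in law.
#' @param noiseSd white-noise level added to every EEG channel (uV).
#' @param modSd baseline modulation standard deviation (class G).
#' @param seed integer.
#' @return list with `recordings` (list of [Recording-class], two per
#'   subject: baseline then task) and `labels` (data.frame with
#'   `subject_id`, `quality`, `n_subtractions`, `age`, `gender`).
#' @examples
#' out <- synthesizeRecordings(nGood = 2, nBad = 2, fs = 64,
#'                             durationTask = 3, durationBaseline = 3,
#'                             channels = eegmatMontage()[c(1, 21)])
#' length(out$recordings)  # 8 = 2 trials x 4 subjects
#' @export
synthesizeRecordings <- function(nGood = 10L, nBad = 10L, fs = 128,
                                 durationTask = 60, durationBaseline = 180,
                                 channels = eegmatMontage(),
                                 bands = .default_bands(),
                                 effectSize = 1, noiseSd = 2, modSd = 0.5,
                                 seed = 1L) {
  stopifnot(nGood >= 1L, nBad >= 1L, fs > 0, durationTask > 0,
            durationBaseline > 0, effectSize >= 0, modSd >= 0)
  channels <- as.character(channels)
  if (length(channels) < 1L || anyDuplicated(channels))
    stop("invalid montage: channel names must be non-empty and unique")
  if (any(bands$center >= fs / 2))
    stop("invalid band specification: centers must be below fs/2 = ", fs / 2)

  qual <- c(rep("G", nGood), rep("B", nBad))
  ids <- sprintf("sub%02d", seq_along(qual))
  .with_seed(seed, {
    labels <- data.frame(
      subject_id = ids, quality = qual,
      n_subtractions = ifelse(qual == "G", stats::rpois(length(qual), 21),
                              stats::rpois(length(qual), 7)),
      age = sample(16:26, length(qual), replace = TRUE),
      gender = sample(c("F", "M"), length(qual), replace = TRUE),
      stringsAsFactors = FALSE)

    recordings <- list()
    for (i in seq_along(ids)) {
      sdMod <- modSd * if (qual[i] == "B") sqrt(1 + effectSize) else 1
      for (tr in c("baseline", "task")) {
        dur <- if (tr == "baseline") durationBaseline else durationTask
        n <- round(fs * dur)
        t <- seq_len(n) / fs
        x <- matrix(0, length(channels), n,
                    dimnames = list(channels, NULL))
        for (ch in channels) {
          if (grepl("ECG", ch, fixed = TRUE)) {
            x[ch, ] <- .ecg_trace(n, fs)
          } else {
            sig <- noiseSd * stats::rnorm(n)
            for (b in seq_len(nrow(bands))) {
              env <- 1 + sdMod * .smooth_noise(n, fs, bands$mod_rate[b])
              sig <- sig + bands$amplitude[b] * env *
                cos(2 * pi * bands$center[b] * t + stats::runif(1, 0, 2 * pi))
            }
            x[ch, ] <- sig
          }
        }
        recordings[[length(recordings) + 1L]] <- Recording(ids[i], tr, x, fs)
      }
    }
    list(recordings = recordings, labels = labels)
  })
}

#' Write synthetic recordings as an EDF + CSV fixture
#'
#' Lays the data out exactly as [readRecording()]/[readLabels()] expect:
#' one EDF per subject-trial named `<subject>_1.edf` (baseline) or
#' `<subject>_2.edf` (task), plus `subject-info.csv` using the public
#' table's column names (`Subject`, `Age`, `Gender`,
#' `Number of subtractions`, `Count quality` with the 0/1 coding).
#' Reading the files back reproduces channel names, sampling rate and
#' labels exactly, and samples to EDF's 16-bit quantisation.
#'
#' @param recordings list of [Recording-class].
#' @param labels label data.frame from [synthesizeRecordings()].
#' @param dir writable output directory (created if missing).
#' @return character vector of the written file paths, invisibly.
#' @export
writeFixture <- function(recordings, labels, dir) {
  if (!dir.exists(dir))
    if (!dir.create(dir, recursive = TRUE))
      stop("cannot create fixture directory '", dir, "'")
  paths <- vapply(recordings, function(rec) {
    p <- file.path(dir, sprintf("%s_%d.edf", subjectId(rec),
                                if (trial(rec) == "baseline") 1L else 2L))
    writeRecording(rec, p)
    p
  }, "")
  lab <- data.frame(
    Subject = labels$subject_id,
    Age = if (!is.null(labels$age)) labels$age else NA,
    Gender = if (!is.null(labels$gender)) labels$gender else NA,
    `Number of subtractions` =
      if (!is.null(labels$n_subtractions)) labels$n_subtractions else NA,
    `Count quality` = ifelse(labels$quality == "G", 1L, 0L),
    check.names = FALSE)
  labPath <- file.path(dir, "subject-info.csv")
  utils::write.csv(lab, labPath, row.names = FALSE, quote = FALSE)
  invisible(c(paths, labPath))
}
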