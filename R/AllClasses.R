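#' @import methods
NULL

#' Recording: one subject-trial multichannel biosignal
#'
#' Container for a single subject-trial recording: a channels-by-time
#' sample matrix (microvolts for EEG channels, millivolts for ECG) with
#' channel names as row names, plus sampling rate and identifying
#' metadata. Recordings are produced by [readRecording()] (EDF files) or
#' [synthesizeRecordings()] and consumed by [decomposeRecording()].
#'
#' @slot subjectId character(1), subject identifier.
#' @slot trial character(1), `"baseline"` (acclimatisation run) or
#'   `"task"` (mental-arithmetic run).
#' @slot samples numeric matrix, channels x time; row names are the
#'   channel labels.
#' @slot fs numeric(1), sampling rate in Hz.
#'
#' @seealso [Recording()] for the user-facing constructor,
#'   [channelNames()], [samplingRate()], [nSamples()], [duration()].
#' @export
setClass("Recording",
  representation(
    subjectId = "character",
    trial     = "character",
    samples   = "matrix",
    fs        = "numeric"
  )
)

setValidity("Recording", function(object) {
  msg <- character()
  if (length(object@subjectId) != 1L || !nzchar(object@subjectId))
    msg <- c(msg, "subjectId must be a single non-empty string")
  if (length(object@trial) != 1L || !object@trial %in% c("baseline", "task"))
    msg <- c(msg, "trial must be 'baseline' or 'task'")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (!is.numeric(object@samples))
    msg <- c(msg, "samples must be a numeric matrix")
  cn <- rownames(object@samples)
  if (is.null(cn) || anyNA(cn) || any(!nzchar(cn)))
    msg <- c(msg, "samples must have non-empty channel row names")
  else if (anyDuplicated(cn))
    msg <- c(msg, "channel names must be unique")
  if (ncol(object@samples) < 1L)
    msg <- c(msg, "recording must contain at least one sample")
  if (length(msg)) msg else TRUE
})

#' Construct a Recording
#'
#' @param subjectId character(1) subject identifier.
#' @param trial `"baseline"` or `"task"`.
#' @param samples numeric matrix, channels x time.
#' @param fs sampling rate in Hz (positive).
#' @param channelNames optional character vector of channel labels; if
#'   omitted the row names of `samples` are used.
#'
#' @return A [Recording-class] object. Its duration in seconds is
#'   `ncol(samples) / fs`, so the shape contract
#'   `nSamples(rec) == round(fs * duration(rec))` holds by construction.
#' @examples
#' rec <- Recording("sub01", "task",
#'                  matrix(rnorm(2 * 100), 2, 100,
#'                         dimnames = list(c("EEG Fp1", "EEG Fp2"), NULL)),
#'                  fs = 50)
#' duration(rec)
#' @export
Recording <- function(subjectId, trial, samples, fs, channelNames = NULL) {
  trial <- match.arg(trial, c("baseline", "task"))
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (!is.null(channelNames)) {
    if (length(channelNames) != nrow(samples))
      stop("channelNames length (", length(channelNames),
           ") does not match channel count (", nrow(samples), ")")
    rownames(samples) <- channelNames
  }
  new("Recording", subjectId = as.character(subjectId), trial = trial,
      samples = samples, fs = as.numeric(fs))
}

#' VMDResult: one channel's variational mode decomposition
#'
#' Holds the K band-limited modes extracted from a single-channel signal
#' by [vmd()], their center frequencies (Hz, ascending), convergence
#' diagnostics, and the reconstruction residual (input minus the column
#' sum of the modes, exact by construction).
#'
#' @slot modes numeric matrix, K x N; row k is mode k in the input units.
#' @slot centerFreqs numeric(K), spectral centroids in Hz, ascending,
#'   each in `[0, fs/2]`.
#' @slot fs numeric(1), sampling rate of the decomposed signal.
#' @slot nIter integer(1), ADMM iterations used.
#' @slot converged logical(1), whether the relative-change criterion was
#'   met before the iteration cap.
#' @slot residual numeric(N), input minus sum of modes.
#' @export
setClass("VMDResult",
  representation(
    modes       = "matrix",
    centerFreqs = "numeric",
    fs          = "numeric",
    nIter       = "integer",
    converged   = "logical",
    residual    = "numeric"
  )
)

setValidity("VMDResult", function(object) {
  msg <- character()
  if (nrow(object@modes) != length(object@centerFreqs))
    msg <- c(msg, "one center frequency per mode is required")
  if (length(object@residual) != ncol(object@modes))
    msg <- c(msg, "residual length must equal the mode length")
  if (length(object@fs) != 1L || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  cf <- object@centerFreqs
  if (any(cf < -1e-9) || any(cf > object@fs / 2 + 1e-9))
    msg <- c(msg, "center frequencies must lie in [0, fs/2]")
  if (is.unsorted(cf, strictly = FALSE))
    msg <- c(msg, "modes must be ordered by ascending center frequency")
  if (length(msg)) msg else TRUE
})

#' PoincarePlot: second-order difference plot of a signal
#'
#' The scatter of consecutive first differences of a source sequence x:
#' `X(t) = x(t+1) - x(t)` against `Y(t) = x(t+2) - x(t+1)`. Built by
#' [poincarePlot()]; its dispersion is summarised by
#' [ellipseDescriptor()], [meanDistance()] and [ctm()].
#'
#' @slot X numeric, successive first differences.
#' @slot Y numeric, the same differences shifted by one step.
#' @export
setClass("PoincarePlot",
  representation(X = "numeric", Y = "numeric")
)

setValidity("PoincarePlot", function(object) {
  if (length(object@X) != length(object@Y))
    return("X and Y must have equal length")
  TRUE
})

#' DecomposedRecording: per-channel VMD of one recording
#'
#' The result of [decomposeRecording()]: one [VMDResult-class] per
#' channel of a [Recording-class], keeping the subject/trial identity so
#' feature tables can be assembled downstream.
#'
#' @slot subjectId character(1).
#' @slot trial character(1), `"baseline"` or `"task"`.
#' @slot fs numeric(1), sampling rate in Hz.
#' @slot decompositions named list of [VMDResult-class], one per channel.
#' @export
setClass("DecomposedRecording",
  representation(
    subjectId      = "character",
    trial          = "character",
    fs             = "numeric",
    decompositions = "list"
  )
)

setValidity("DecomposedRecording", function(object) {
  msg <- character()
  nm <- names(object@decompositions)
  if (is.null(nm) || anyDuplicated(nm))
    msg <- c(msg, "decompositions must be a uniquely named list")
  if (!all(vapply(object@decompositions, is, logical(1), "VMDResult")))
    msg <- c(msg, "all decompositions must be VMDResult objects")
  if (length(msg)) msg else TRUE
})
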