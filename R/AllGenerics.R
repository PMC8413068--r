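#' Accessors for Recording and decomposition objects
#'
#' Slot access goes through these generics; user code should never reach
#' into slots directly.
#'
#' @param object a [Recording-class], [VMDResult-class],
#'   [PoincarePlot-class] or [DecomposedRecording-class].
#' @return `channelNames()` a character vector; `samplingRate()` and
#'   `duration()` single numbers (Hz and seconds); `samples()` the
#'   channels-by-time matrix; `subjectId()`/`trial()` single strings;
#'   `nSamples()` the per-channel sample count; `modes()` the K x N mode
#'   matrix; `centerFreqs()` the center frequencies in Hz; `nIterations()`
#'   the ADMM iteration count; `converged()` a logical flag;
#'   `decompositions()` the named per-channel list of VMD results.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))
#' @rdname accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("trial", function(object) standardGeneric("trial"))
#' @rdname accessors
#' @export
setGeneric("duration", function(object) standardGeneric("duration"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("modes", function(object) standardGeneric("modes"))
#' @rdname accessors
#' @export
setGeneric("centerFreqs", function(object) standardGeneric("centerFreqs"))
#' @rdname accessors
#' @export
setGeneric("nIterations", function(object) standardGeneric("nIterations"))
#' @rdname accessors
#' @export
setGeneric("converged", function(object) standardGeneric("converged"))
#' @rdname accessors
#' @export
setGeneric("decompositions", function(object) standardGeneric("decompositions"))

#' @rdname accessors
#' @export
setMethod("channelNames", "Recording", function(object) rownames(object@samples))
#' @rdname accessors
#' @export
setMethod("samplingRate", "Recording", function(object) object@fs)
#' @rdname accessors
#' @export
setMethod("samples", "Recording", function(object) object@samples)
#' @rdname accessors
#' @export
setMethod("subjectId", "Recording", function(object) object@subjectId)
#' @rdname accessors
#' @export
setMethod("trial", "Recording", function(object) object@trial)
#' @rdname accessors
#' @export
setMethod("duration", "Recording", function(object) ncol(object@samples) / object@fs)
#' @rdname accessors
#' @export
setMethod("nSamples", "Recording", function(object) ncol(object@samples))

#' @rdname accessors
#' @export
setMethod("modes", "VMDResult", function(object) object@modes)
#' @rdname accessors
#' @export
setMethod("centerFreqs", "VMDResult", function(object) object@centerFreqs)
#' @rdname accessors
#' @export
setMethod("samplingRate", "VMDResult", function(object) object@fs)
#' @rdname accessors
#' @export
setMethod("nIterations", "VMDResult", function(object) object@nIter)
#' @rdname accessors
#' @export
setMethod("converged", "VMDResult", function(object) object@converged)
#' @rdname accessors
#' @param ... unused.
#' @export
setMethod("residuals", "VMDResult", function(object, ...) object@residual)

#' @rdname accessors
#' @export
setMethod("subjectId", "DecomposedRecording", function(object) object@subjectId)
#' @rdname accessors
#' @export
setMethod("trial", "DecomposedRecording", function(object) object@trial)
#' @rdname accessors
#' @export
setMethod("samplingRate", "DecomposedRecording", function(object) object@fs)
#' @rdname accessors
#' @export
setMethod("channelNames", "DecomposedRecording",
          function(object) names(object@decompositions))
#' @rdname accessors
#' @export
setMethod("decompositions", "DecomposedRecording",
          function(object) object@decompositions)

setMethod("show", "Recording", function(object) {
  cat("Recording: subject", object@subjectId,
      sprintf("(%s trial)\n", object@trial))
  cat(sprintf("  %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(object@samples), ncol(object@samples), object@fs,
              ncol(object@samples) / object@fs))
  cn <- rownames(object@samples)
  cat("  channels:", paste(utils::head(cn, 6), collapse = ", "),
      if (length(cn) > 6) sprintf("... (%d more)", length(cn) - 6) else "",
      "\n")
})

setMethod("show", "VMDResult", function(object) {
  cat(sprintf("VMDResult: %d modes x %d samples @ %g Hz\n",
              nrow(object@modes), ncol(object@modes), object@fs))
  cat("  center frequencies (Hz):",
      paste(sprintf("%.2f", object@centerFreqs), collapse = ", "), "\n")
  cat(sprintf("  %s after %d iterations; residual RMS %.3g\n",
              if (object@converged) "converged" else "NOT converged",
              object@nIter, sqrt(mean(object@residual^2))))
})

setMethod("show", "PoincarePlot", function(object) {
  cat(sprintf("PoincarePlot: %d points\n", length(object@X)))
})

setMethod("show", "DecomposedRecording", function(object) {
  cat("DecomposedRecording: subject", object@subjectId,
      sprintf("(%s trial), %d channels @ %g Hz\n",
              object@trial, length(object@decompositions), object@fs))
})

#' Number of points in a Poincare plot
#' @param x a [PoincarePlot-class].
#' @return integer point count.
#' @export
setMethod("length", "PoincarePlot", function(x) length(x@X))
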