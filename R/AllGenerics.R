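#' Accessors for wpliNet classes
#'
#' Small accessor generics so user code never touches slots directly:
#' \code{channelData} returns the numeric data (matrix or array),
#' \code{samplingRate} the sampling rate in Hz, \code{channelLabels} the
#' channel labels, \code{eogLabels} the EOG subset, \code{conditions} the
#' per-trial or per-event condition table, \code{provenance} the operation
#' log, \code{connMatrix} the numeric WPLI matrix, and \code{bandInfo} the
#' band definition attached to an object.
#'
#' @param x a wpliNet object.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("channelData", function(x) standardGeneric("channelData"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))
#' @rdname accessors
#' @export
setGeneric("eogLabels", function(x) standardGeneric("eogLabels"))
#' @rdname accessors
#' @export
setGeneric("conditions", function(x) standardGeneric("conditions"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("connMatrix", function(x) standardGeneric("connMatrix"))
#' @rdname accessors
#' @export
setGeneric("bandInfo", function(x) standardGeneric("bandInfo"))
#' @rdname accessors
#' @export
setGeneric("rejectedMask", function(x) standardGeneric("rejectedMask"))

#' @rdname accessors
#' @export
setMethod("channelData", "EEGRecording", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("channelData", "EEGEpochs", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("samplingRate", "EEGRecording", function(x) x@fs)
#' @rdname accessors
#' @export
setMethod("samplingRate", "EEGEpochs", function(x) x@fs)
#' @rdname accessors
#' @export
setMethod("channelLabels", "EEGRecording", function(x) x@channelLabels)
#' @rdname accessors
#' @export
setMethod("channelLabels", "EEGEpochs", function(x) x@channelLabels)
#' @rdname accessors
#' @export
setMethod("channelLabels", "SpectralSummary", function(x) x@channelLabels)
#' @rdname accessors
#' @export
setMethod("channelLabels", "ConnectivityMatrix", function(x) rownames(x@W))
#' @rdname accessors
#' @export
setMethod("eogLabels", "EEGRecording", function(x) x@eogLabels)
#' @rdname accessors
#' @export
setMethod("eogLabels", "EEGEpochs", function(x) x@eogLabels)
#' @rdname accessors
#' @export
setMethod("conditions", "EEGRecording", function(x) x@events)
#' @rdname accessors
#' @export
setMethod("conditions", "EEGEpochs", function(x) x@conditions)
#' @rdname accessors
#' @export
setMethod("provenance", "EEGRecording", function(x) x@provenance)
#' @rdname accessors
#' @export
setMethod("provenance", "EEGEpochs", function(x) x@provenance)
#' @rdname accessors
#' @export
setMethod("connMatrix", "ConnectivityMatrix", function(x) x@W)
#' @rdname accessors
#' @export
setMethod("bandInfo", "ConnectivityMatrix", function(x) x@band)
#' @rdname accessors
#' @export
setMethod("bandInfo", "CrossSpectralSamples", function(x) x@band)
#' @rdname accessors
#' @export
setMethod("rejectedMask", "EEGEpochs", function(x) x@rejected)

#' @describeIn accessors number of scalp (non-EOG) channels.
#' @export
scalpLabels <- function(x) setdiff(channelLabels(x), eogLabels(x))

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(object@data), ncol(object@data), object@fs,
              ncol(object@data) / object@fs))
  cat(sprintf("  reference: %s | EOG: %s | events: %d\n",
              object@reference,
              if (length(object@eogLabels)) paste(object@eogLabels, collapse = ",") else "none",
              nrow(object@events)))
  cat(sprintf("  provenance: %s\n",
              if (length(object@provenance))
                paste(vapply(object@provenance, `[[`, "", "op"), collapse = " -> ")
              else "raw"))
})

setMethod("show", "EEGEpochs", function(object) {
  d <- dim(object@data)
  cat(sprintf("EEGEpochs: %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], object@fs))
  cat(sprintf("  window [%g, %g] s; rejected %d/%d trials\n",
              object@window[1], object@window[2], sum(object@rejected), d[1]))
})

setMethod("show", "ConnectivityMatrix", function(object) {
  off <- object@W[upper.tri(object@W)]
  cat(sprintf("ConnectivityMatrix (%s %g-%g Hz%s): %d nodes, mean WPLI %.3f\n",
              object@band$name, object@band$lo, object@band$hi,
              if (length(object@condition))
                paste0(", ", paste(object@condition, collapse = "/")) else "",
              nrow(object@W), mean(off)))
})

setMethod("show", "NetworkMetrics", function(object) {
  cat(sprintf(paste0(
    "NetworkMetrics: N=%d | strength %.3f | clustering %.3f | ",
    "L %.3f | E_glob %.3f | E_loc %.3f\n"),
    length(object@strength), object@meanStrength, object@meanClustering,
    object@charPathLength, object@globalEfficiency, object@localEfficiency))
  if (object@nUnreachable > 0L)
    cat(sprintf("  (%d unreachable ordered pairs excluded from L)\n", object@nUnreachable))
})

setMethod("show", "SpectralSummary", function(object) {
  cat(sprintf("SpectralSummary: %d channels, %d frequency bins (%.2f-%.2f Hz)\n",
              nrow(object@psd), length(object@freqs),
              min(object@freqs), max(object@freqs)))
  if (ncol(object@bandPower))
    cat("  bands:", paste(colnames(object@bandPower), collapse = ", "), "\n")
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: %d subjects, %d channels @ %g Hz, %g s trials, %d/cell\n",
              object@nSubjects, object@nChannels, object@fs, object@trialSec,
              object@nTrialsPerCell))
  for (bn in names(object@bandCoupling)) {
    g <- object@bandCoupling[[bn]]
    cat(sprintf("  %s: g(nostalgic)=%.2f g(non-nostalgic)=%.2f\n",
                bn, g[["nostalgic"]], g[["non-nostalgic"]]))
  }
})
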