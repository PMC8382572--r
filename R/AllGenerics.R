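## Generics and accessors for the S4 containers, plus show() methods.

#' @describeIn StimulusSequence-class event table accessor
#' @param x,object a `StimulusSequence`
#' @export
setGeneric("events", function(x) standardGeneric("events"))

#' @export
setMethod("events", "StimulusSequence", function(x) x@events)

#' @describeIn RawRecording-class sampling rate (Hz)
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @export
setMethod("sampleRate", "RawRecording", function(x) x@sampleRate)

#' @export
setMethod("sampleRate", "EpochSet", function(x) x@sampleRate)

#' @describeIn RawRecording-class channel labels
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @export
setMethod("channelNames", "RawRecording", function(x) rownames(x@data))

#' @export
setMethod("channelNames", "EpochSet", function(x) x@channels)

#' @describeIn RawRecording-class channels x samples data matrix (uV)
#' @export
setGeneric("eegData", function(x) standardGeneric("eegData"))

#' @export
setMethod("eegData", "RawRecording", function(x) x@data)

#' @describeIn RawRecording-class stimulus markers
#' @export
setGeneric("markers", function(x) standardGeneric("markers"))

#' @export
setMethod("markers", "RawRecording", function(x) x@markers)

#' @describeIn EpochSet-class number of epochs (kept + rejected)
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))

#' @export
setMethod("nEpochs", "EpochSet", function(x) length(x@epochs))

#' @describeIn EpochSet-class per-epoch rejection flags
#' @export
setGeneric("isRejected", function(x) standardGeneric("isRejected"))

#' @export
setMethod("isRejected", "EpochSet", function(x) x@rejected)

#' @describeIn EpochSet-class per-epoch condition labels
#' @export
setGeneric("epochConditions", function(x) standardGeneric("epochConditions"))

#' @export
setMethod("epochConditions", "EpochSet", function(x) x@condition)

#' @describeIn ErpMeasurementSet-class the six measures (named numeric)
#' @export
setGeneric("measures", function(x) standardGeneric("measures"))

#' @export
setMethod("measures", "ErpMeasurementSet", function(x) x@measures)

#' @describeIn ErpMeasurementSet-class QC status
#' @export
setGeneric("qcStatus", function(x) standardGeneric("qcStatus"))

#' @export
setMethod("qcStatus", "ErpMeasurementSet", function(x) x@qc)

#' @describeIn ErpMeasurementSet-class fraction of epochs rejected
#' @export
setGeneric("rejectionFraction", function(x) standardGeneric("rejectionFraction"))

#' @export
setMethod("rejectionFraction", "ErpMeasurementSet", function(x) x@rejectionFraction)

#' @describeIn ReferenceDistribution-class the per-measure statistics table
#' @export
setGeneric("refStats", function(x) standardGeneric("refStats"))

#' @export
setMethod("refStats", "ReferenceDistribution", function(x) x@stats)

#' @describeIn StandardizedProfile-class the six 0-100 scores
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @export
setMethod("scores", "StandardizedProfile", function(x) x@scores)

#' @describeIn StandardizedProfile-class the underlying z-values
#' @export
setGeneric("zValues", function(x) standardGeneric("zValues"))

#' @export
setMethod("zValues", "StandardizedProfile", function(x) x@z)

## ---- show methods -------------------------------------------------------

setMethod("show", "StimulusSequence", function(object) {
  ev <- object@events
  cat("StimulusSequence with", nrow(ev), "events\n")
  if (nrow(ev)) {
    tab <- table(ev$kind)
    cat("  kinds:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
    cat(sprintf("  span: %.3f - %.3f s\n", min(ev$onset), max(ev$onset)))
  }
})

setMethod("show", "RawRecording", function(object) {
  cat(sprintf("RawRecording: %d channels (%s), %d samples @ %g Hz (%.1f s)\n",
              nrow(object@data), paste(rownames(object@data), collapse = ", "),
              ncol(object@data), object@sampleRate,
              ncol(object@data) / object@sampleRate))
  cat("  markers:", nrow(object@markers@events), "events\n")
})

setMethod("show", "EpochSet", function(object) {
  cat(sprintf("EpochSet: %d epochs [%g, %g] ms, %d rejected, %d dropped at edges\n",
              length(object@epochs), object@windowMs[1], object@windowMs[2],
              sum(object@rejected), object@nDropped))
  if (length(object@condition))
    print(table(condition = object@condition, rejected = object@rejected))
})

setMethod("show", "ErpMeasurementSet", function(object) {
  cat(sprintf("ErpMeasurementSet: participant %s, session %d [%s]\n",
              object@participantId, object@session, object@qc))
  m <- object@measures
  cat(sprintf("  N100 %.2f uV @ %g ms | P300 %.2f uV @ %g ms | N400 %.2f uV @ %g ms\n",
              m[1], m[2], m[3], m[4], m[5], m[6]))
  cat(sprintf("  rejection fraction: %.3f\n", object@rejectionFraction))
})

setMethod("show", "ReferenceDistribution", function(object) {
  cat("ReferenceDistribution over", nrow(object@stats), "measures\n")
  print(object@stats, row.names = FALSE)
})

setMethod("show", "StandardizedProfile", function(object) {
  cat("StandardizedProfile", if (length(object@label)) object@label else "", "\n")
  print(round(object@scores, 1))
})
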