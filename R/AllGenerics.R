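#' Accessors for tmjseg objects
#'
#' Slot accessors for [AudioRecord-class], [AnnotatedRecord-class] and
#' [SegmentationModel-class] objects.
#'
#' @param x an object.
#' @return `samples()` the amplitude vector; `sampleRate()` the sampling
#'   rate in Hz; `nSamples()` the signal length; `patientId()`, `side()`,
#'   `diagnosis()` the metadata strings; `mask()` the integer 0/1 label
#'   vector; `audioRecord()` the embedded [AudioRecord-class];
#'   `modelConfigOf()` the architecture configuration list.
#' @name accessors
#' @aliases samples sampleRate nSamples patientId side diagnosis mask
#'   audioRecord modelConfigOf
#' @examples
#' rec <- AudioRecord(rnorm(100) / 10)
#' sampleRate(rec)
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))
#' @rdname accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))
#' @rdname accessors
#' @export
setGeneric("side", function(x) standardGeneric("side"))
#' @rdname accessors
#' @export
setGeneric("diagnosis", function(x) standardGeneric("diagnosis"))
#' @rdname accessors
#' @export
setGeneric("mask", function(x) standardGeneric("mask"))
#' @rdname accessors
#' @export
setGeneric("audioRecord", function(x) standardGeneric("audioRecord"))
#' @rdname accessors
#' @export
setGeneric("modelConfigOf", function(x) standardGeneric("modelConfigOf"))

#' @rdname accessors
setMethod("samples", "AudioRecord", function(x) x@samples)
#' @rdname accessors
setMethod("sampleRate", "AudioRecord", function(x) x@fs)
#' @rdname accessors
setMethod("nSamples", "AudioRecord", function(x) length(x@samples))
#' @rdname accessors
setMethod("patientId", "AudioRecord", function(x) x@patientId)
#' @rdname accessors
setMethod("side", "AudioRecord", function(x) x@side)
#' @rdname accessors
setMethod("diagnosis", "AudioRecord", function(x) x@diagnosis)

#' @rdname accessors
setMethod("samples", "AnnotatedRecord", function(x) x@record@samples)
#' @rdname accessors
setMethod("sampleRate", "AnnotatedRecord", function(x) x@record@fs)
#' @rdname accessors
setMethod("nSamples", "AnnotatedRecord", function(x) length(x@record@samples))
#' @rdname accessors
setMethod("patientId", "AnnotatedRecord", function(x) x@record@patientId)
#' @rdname accessors
setMethod("side", "AnnotatedRecord", function(x) x@record@side)
#' @rdname accessors
setMethod("diagnosis", "AnnotatedRecord", function(x) x@record@diagnosis)
#' @rdname accessors
setMethod("mask", "AnnotatedRecord", function(x) x@mask)
#' @rdname accessors
setMethod("audioRecord", "AnnotatedRecord", function(x) x@record)

#' @rdname accessors
setMethod("modelConfigOf", "SegmentationModel", function(x) x@config)

setMethod("show", "AudioRecord", function(object) {
  cat(sprintf(
    "AudioRecord: %d samples at %g Hz (%.2f s), patient '%s', %s side, %s\n",
    length(object@samples), object@fs,
    length(object@samples) / object@fs,
    object@patientId, object@side, object@diagnosis))
})

setMethod("show", "AnnotatedRecord", function(object) {
  m <- object@mask
  segs <- maskToSegments(m)
  cat(sprintf(
    "AnnotatedRecord: %d samples at %g Hz, patient '%s' (%s, %s)\n",
    length(m), object@record@fs, object@record@patientId,
    object@record@side, object@record@diagnosis))
  cat(sprintf("  %d annotated segment(s), %.1f%% of samples positive\n",
              length(segs), 100 * mean(m)))
})

setMethod("show", "SegmentationModel", function(object) {
  cfg <- object@config
  numel <- function(x) if (is.list(x)) sum(vapply(x, numel, numeric(1))) else length(x)
  np <- numel(object@params)
  cat("SegmentationModel (1D U-Net, min-abs pooling, LSTM bottleneck)\n")
  cat(sprintf("  input length: %d samples, pool window: %d per block\n",
              cfg$inputLen, cfg$poolWindow))
  cat(sprintf("  conv channels: (%s), kernel %d; %d LSTM layer(s) of %d units\n",
              paste(cfg$channels, collapse = ", "), cfg$kernelSize,
              cfg$lstmLayers, cfg$lstmHidden))
  cat(sprintf("  %d trainable parameters\n", np))
})
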