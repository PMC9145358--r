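#' @import methods
#' @importFrom stats fft rnorm runif
#' @importFrom utils read.csv write.csv head tail
#' @importFrom IRanges IRanges start end reduce isDisjoint
#' @importFrom S4Vectors Rle
NULL

.SIDES <- c("left", "right")
.DIAGNOSES <- c("healthy", "tmd", "unknown")

#' AudioRecord: a mono auscultation signal
#'
#' An S4 container for a single-channel acoustic recording of the
#' temporomandibular joint (TMJ), as captured by an electronic stethoscope.
#' Amplitudes are dimensionless real values in \eqn{[-1, 1]} (full-scale
#' normalized PCM); the sampling rate of the source corpus is 4000 Hz.
#'
#' @slot samples numeric vector of amplitudes.
#' @slot fs sampling rate in Hz.
#' @slot patientId opaque patient identifier.
#' @slot side auscultation side, `"left"` or `"right"`.
#' @slot diagnosis `"healthy"`, `"tmd"` or `"unknown"`.
#'
#' @seealso [readWav()], [generateRecord()]
#' @export
setClass("AudioRecord",
  representation(
    samples = "numeric",
    fs = "numeric",
    patientId = "character",
    side = "character",
    diagnosis = "character"
  ),
  prototype(fs = 4000, patientId = "unknown", side = "left",
            diagnosis = "unknown")
)

setValidity("AudioRecord", function(object) {
  msg <- character(0)
  if (length(object@samples) < 1L)
    msg <- c(msg, "samples must be non-empty")
  if (any(!is.finite(object@samples)))
    msg <- c(msg, "samples must all be finite")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (length(object@side) != 1L || !object@side %in% .SIDES)
    msg <- c(msg, "side must be 'left' or 'right'")
  if (length(object@diagnosis) != 1L || !object@diagnosis %in% .DIAGNOSES)
    msg <- c(msg, "diagnosis must be 'healthy', 'tmd' or 'unknown'")
  if (length(msg)) msg else TRUE
})

#' Construct an AudioRecord
#'
#' @param samples numeric vector of amplitudes (finite, non-empty).
#' @param fs sampling rate in Hz (default 4000, the corpus rate).
#' @param patientId opaque patient identifier string.
#' @param side `"left"` or `"right"`.
#' @param diagnosis `"healthy"`, `"tmd"` or `"unknown"`.
#' @return An [AudioRecord-class] object.
#' @examples
#' rec <- AudioRecord(sin(2 * pi * 5 * seq(0, 1, by = 1 / 4000)))
#' nSamples(rec)
#' @export
AudioRecord <- function(samples, fs = 4000, patientId = "unknown",
                        side = "left", diagnosis = "unknown") {
  new("AudioRecord", samples = as.numeric(samples), fs = fs,
      patientId = patientId, side = side, diagnosis = diagnosis)
}

#' AnnotatedRecord: a signal paired with its sample-wise segment mask
#'
#' Couples an [AudioRecord-class] with a reference mask labelling every
#' sample `1` when it belongs to a jaw open/close episode and `0` otherwise.
#'
#' @slot record the [AudioRecord-class].
#' @slot mask integer vector of 0/1 labels, one per sample.
#' @seealso [readAnnotationCsv()], [generateRecord()]
#' @export
setClass("AnnotatedRecord",
  representation(record = "AudioRecord", mask = "integer")
)

setValidity("AnnotatedRecord", function(object) {
  msg <- character(0)
  if (length(object@mask) != length(object@record@samples))
    msg <- c(msg, "mask length must equal the number of samples")
  if (any(!object@mask %in% c(0L, 1L)))
    msg <- c(msg, "mask labels must all be 0 or 1")
  if (length(msg)) msg else TRUE
})

#' Construct an AnnotatedRecord
#'
#' @param record an [AudioRecord-class].
#' @param mask vector of 0/1 labels, same length as the signal.
#' @return An [AnnotatedRecord-class].
#' @export
AnnotatedRecord <- function(record, mask) {
  new("AnnotatedRecord", record = record, mask = as.integer(mask))
}

#' SegmentationModel: the 1D U-Net/LSTM segmentation network
#'
#' Holds the architecture configuration and the parameter tensors of the
#' modified one-dimensional U-Net: two convolutional blocks whose pooling
#' stage runs max pooling and min-absolute pooling in parallel
#' (concatenated on the channel axis), a bottleneck of stacked LSTM layers
#' operating along the decimated time axis, and a decoder that restores the
#' input length by zero-insertion up-sampling followed by learned
#' convolutions, with U-Net skip connections. The final layer is a
#' per-sample sigmoid, so the network maps a signal window to a per-sample
#' probability of lying inside a jaw open/close episode.
#'
#' @slot config list of architecture settings, see [modelConfig()].
#' @slot params named list of weight arrays.
#' @seealso [buildModel()], [trainModel()], [predictMask()]
#' @export
setClass("SegmentationModel",
  representation(config = "list", params = "list")
)
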