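#' Read a mono 16-bit PCM WAV file
#'
#' Decodes a RIFF/WAVE file into an [AudioRecord-class]. Only single-channel
#' integer PCM at 16 bits per sample is accepted, matching the electronic
#' stethoscope source format; stereo or non-PCM files are rejected rather
#' than down-mixed. Integer sample values are mapped to real amplitudes by
#' division by 32768 (the type's full scale), so the decoded range is
#' \eqn{[-1, 1)}.
#'
#' @param path path to a WAV file.
#' @param patientId,side,diagnosis optional metadata attached to the result.
#' @return An [AudioRecord-class] with `fs` taken from the file header.
#' @seealso [writeWav()]
#' @export
readWav <- function(path, patientId = "unknown", side = "left",
                    diagnosis = "unknown") {
  if (!file.exists(path))
    stop("WAV file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF"))
    stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")  # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE"))
    stop("not a WAVE file: ", path)

  fs <- NULL; bits <- NULL; channels <- NULL; fmt <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 1, size = 2, endian = "little",
                     signed = FALSE)
      channels <- readBin(con, "integer", 1, size = 2, endian = "little",
                          signed = FALSE)
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")  # byte rate
      readBin(con, "integer", 1, size = 2, endian = "little")  # block align
      bits <- readBin(con, "integer", 1, size = 2, endian = "little",
                      signed = FALSE)
      if (sz > 16) readBin(con, "raw", sz - 16)
    } else if (identical(id, "data")) {
      data <- readBin(con, "raw", sz)
      if (sz %% 2 == 1) readBin(con, "raw", 1)  # chunk word padding
    } else {
      readBin(con, "raw", sz + sz %% 2)
    }
    if (!is.null(fmt) && !is.null(data)) break
  }
  if (is.null(fmt) || is.null(data))
    stop("malformed WAV (missing fmt or data chunk): ", path)
  if (fmt != 1L)
    stop("unsupported WAV encoding (only integer PCM is supported)")
  if (channels != 1L)
    stop("unsupported WAV: ", channels, " channels (mono required)")
  if (bits != 16L)
    stop("unsupported WAV: ", bits, "-bit samples (16-bit required)")
  pcm <- readBin(data, "integer", n = length(data) %/% 2L, size = 2,
                 endian = "little", signed = TRUE)
  AudioRecord(pcm / 32768, fs = fs, patientId = patientId, side = side,
              diagnosis = diagnosis)
}

#' Write a mono 16-bit PCM WAV file
#'
#' Quantizes amplitudes to 16-bit integer PCM by round-to-nearest of
#' `32768 * x` (exact ties resolved half-to-even, the IEC 60559 behaviour
#' of [round()]), so [readWav()] followed by `writeWav()` is bit-exact. The
#' single representable exception is an amplitude of exactly +1.0, which is
#' clamped to +32767 (one least-significant bit below full scale).
#' Amplitudes outside \eqn{[-1, 1]} raise an error; there is no silent
#' clipping.
#'
#' @param record an [AudioRecord-class] with samples in \eqn{[-1, 1]}.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeWav <- function(record, path) {
  stopifnot(is(record, "AudioRecord"))
  x <- record@samples
  if (length(x) == 0L)
    stop("cannot write an empty signal")
  if (any(x < -1 | x > 1))
    stop("samples out of range [-1, 1]; refusing to clip")
  pcm <- as.integer(pmin(round(x * 32768), 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")               # PCM
  writeBin(1L, con, size = 2, endian = "little")               # mono
  writeBin(as.integer(record@fs), con, size = 4, endian = "little")
  writeBin(as.integer(record@fs * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")               # block align
  writeBin(16L, con, size = 2, endian = "little")              # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a sample-wise annotation CSV
#'
#' The annotation format pairs every signal sample with a 0/1 label: a
#' header row `amplitude,label` followed by one row per sample. Label `1`
#' marks samples belonging to a jaw open/close episode, `0` all others.
#' The CSV does not carry the sampling rate, so `fs` must be supplied
#' (default 4000 Hz, the corpus rate).
#'
#' @param path path to the CSV file.
#' @param fs sampling rate in Hz of the stored signal.
#' @param patientId,side,diagnosis optional metadata.
#' @return An [AnnotatedRecord-class].
#' @seealso [writeAnnotationCsv()]
#' @export
readAnnotationCsv <- function(path, fs = 4000, patientId = "unknown",
                              side = "left", diagnosis = "unknown") {
  if (!file.exists(path))
    stop("annotation CSV not found: ", path)
  df <- read.csv(path, header = TRUE, colClasses = "numeric")
  if (ncol(df) != 2L)
    stop("annotation CSV must have exactly two columns (amplitude,label), got ",
         ncol(df))
  if (!identical(names(df), c("amplitude", "label")))
    stop("annotation CSV header must be 'amplitude,label'")
  lab <- df$label
  if (any(is.na(lab)) || any(!lab %in% c(0, 1)))
    stop("annotation labels must all be 0 or 1")
  AnnotatedRecord(
    AudioRecord(df$amplitude, fs = fs, patientId = patientId, side = side,
                diagnosis = diagnosis),
    as.integer(lab))
}

#' Write a sample-wise annotation CSV
#'
#' Writes the `amplitude,label` dialect read by [readAnnotationCsv()].
#' Amplitudes are written with full precision (17 significant digits), so
#' the read/write round-trip is value-exact.
#'
#' @param annotated an [AnnotatedRecord-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeAnnotationCsv <- function(annotated, path) {
  stopifnot(is(annotated, "AnnotatedRecord"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("amplitude,label", con)
  writeLines(paste(sprintf("%.17g", samples(annotated)), annotated@mask,
                   sep = ","), con)
  invisible(path)
}

#' Convert a 0/1 mask to segment intervals
#'
#' Maximal runs of `1` become intervals of an [IRanges::IRanges] (1-based,
#' closed ends, the standard R range convention), sorted by start. Inverse
#' of [segmentsToMask()].
#'
#' @param mask integer/numeric vector of 0/1 labels.
#' @return An `IRanges` with one range per annotated episode.
#' @examples
#' maskToSegments(c(0, 1, 1, 0, 1))  # ranges [2,3] and [5,5]
#' @export
maskToSegments <- function(mask) {
  mask <- as.integer(mask)
  if (any(!mask %in% c(0L, 1L)))
    stop("mask labels must all be 0 or 1")
  methods::as(S4Vectors::Rle(mask == 1L), "IRanges")
}

#' Convert segment intervals to a 0/1 mask
#'
#' @param segments an [IRanges::IRanges] of non-overlapping intervals
#'   (1-based, closed) within `[1, length]`.
#' @param length total number of samples.
#' @return Integer vector with `1` exactly inside the intervals.
#' @examples
#' segmentsToMask(IRanges::IRanges(1, 2), 4)  # 1 1 0 0
#' @export
segmentsToMask <- function(segments, length) {
  stopifnot(is(segments, "IRanges"))
  length <- as.integer(length)
  if (length < 0L) stop("length must be non-negative")
  if (base::length(segments) == 0L) return(integer(length))
  if (min(IRanges::start(segments)) < 1L ||
      max(IRanges::end(segments)) > length)
    stop("segments out of range [1, length]")
  if (!IRanges::isDisjoint(segments))
    stop("segments must be non-overlapping")
  m <- integer(length)
  for (i in seq_along(segments)) {
    m[IRanges::start(segments)[i]:IRanges::end(segments)[i]] <- 1L
  }
  m
}
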