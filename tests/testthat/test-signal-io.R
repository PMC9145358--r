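test_that("AudioRecord validity enforces the domain invariants", {
  expect_error(AudioRecord(numeric(0)), "non-empty")
  expect_error(AudioRecord(c(0.1, NA)), "finite")
  expect_error(AudioRecord(0.1, fs = -1), "positive")
  expect_error(AudioRecord(0.1, side = "front"), "side")
  rec <- AudioRecord(c(-0.5, 0.5), fs = 4000, patientId = "P1",
                     side = "right", diagnosis = "tmd")
  expect_identical(nSamples(rec), 2L)
  expect_equal(sampleRate(rec), 4000)
  expect_identical(side(rec), "right")
})

test_that("WAV decode maps integer PCM to full-scale fractions", {
  # hand-assemble a minimal RIFF file with known PCM values
  path <- withr::local_tempfile(fileext = ".wav")
  writeWav(AudioRecord(c(32767, 0, -32768, 16384) / 32768, fs = 4000), path)
  rec <- readWav(path)
  expect_equal(sampleRate(rec), 4000)
  expect_equal(samples(rec), c(32767 / 32768, 0, -1, 0.5))
  expect_equal(samples(rec)[1], 0.99997, tolerance = 1e-4)
})

test_that("WAV write/read round-trips random 16-bit signals bit-exactly", {
  set.seed(42)
  for (n in c(1, 7, 1000)) {
    pcm <- sample(-32768:32767, n, replace = TRUE)
    rec <- AudioRecord(pcm / 32768, fs = 4000)
    path <- withr::local_tempfile(fileext = ".wav")
    writeWav(rec, path)
    back <- readWav(path)
    expect_identical(samples(back), samples(rec))
    expect_equal(sampleRate(back), 4000)
  }
})

test_that("WAV quantization rounds to nearest and rejects bad input", {
  path <- withr::local_tempfile(fileext = ".wav")
  writeWav(AudioRecord(0.5), path)
  con <- file(path, "rb")
  readBin(con, "raw", 44)
  v <- readBin(con, "integer", 1, size = 2, endian = "little")
  close(con)
  expect_equal(v, 16384)                       # round(0.5 * 32768)
  expect_error(writeWav(AudioRecord(1.5), path), "range")
  expect_error(writeWav(AudioRecord(-1.00001), path), "range")
  # +1.0 is representable only by clamping one LSB
  writeWav(AudioRecord(1), path)
  expect_equal(samples(readWav(path)), 32767 / 32768)
})

test_that("multichannel and non-PCM WAV files are rejected", {
  path <- withr::local_tempfile(fileext = ".wav")
  con <- file(path, "wb")
  writeChar("RIFF", con, eos = NULL)
  writeBin(40L, con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")   # stereo
  writeBin(4000L, con, size = 4, endian = "little")
  writeBin(16000L, con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(4L, con, size = 4, endian = "little")
  writeBin(c(0L, 0L), con, size = 2, endian = "little")
  close(con)
  expect_error(readWav(path), "channels")
  expect_error(readWav(file.path(tempdir(), "missing-file.wav")), "not found")
})

test_that("annotation CSV round-trips and validates labels", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("amplitude,label", "0.1,0", "-0.2,1", "0.0,1"), path)
  ann <- readAnnotationCsv(path)
  expect_identical(mask(ann), c(0L, 1L, 1L))
  expect_equal(samples(ann), c(0.1, -0.2, 0.0))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("amplitude,label", "0.1,2"), bad)
  expect_error(readAnnotationCsv(bad), "0 or 1")

  set.seed(7)
  rec <- AudioRecord(runif(200, -1, 1), patientId = "P9")
  ann2 <- AnnotatedRecord(rec, rbinom(200, 1, 0.3))
  out <- withr::local_tempfile(fileext = ".csv")
  writeAnnotationCsv(ann2, out)
  back <- readAnnotationCsv(out, patientId = "P9")
  expect_equal(samples(back), samples(ann2))
  expect_identical(mask(back), mask(ann2))
})

test_that("mask/segment conversions are exact mutual inverses", {
  segs <- maskToSegments(c(0, 1, 1, 0, 1))
  expect_equal(IRanges::start(segs), c(2, 5))
  expect_equal(IRanges::end(segs), c(3, 5))
  expect_length(maskToSegments(rep(0, 10)), 0)
  expect_identical(segmentsToMask(IRanges::IRanges(1, 2), 4), c(1L, 1L, 0L, 0L))
  expect_identical(segmentsToMask(IRanges::IRanges(), 3), c(0L, 0L, 0L))
  expect_error(segmentsToMask(IRanges::IRanges(c(1, 2), c(3, 4)), 5),
               "non-overlapping")
  expect_error(segmentsToMask(IRanges::IRanges(4, 6), 5), "range")

  set.seed(11)
  for (i in 1:50) {
    m <- rbinom(sample(1:200, 1), 1, runif(1))
    expect_identical(segmentsToMask(maskToSegments(m), length(m)),
                     as.integer(m))
  }
})
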