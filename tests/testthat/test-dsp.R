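test_that("rectification normalizes to unit peak and is sign-symmetric", {
  expect_equal(rectifyNormalize(c(-0.5, 0.25, 0)), c(1, 0.5, 0))
  expect_error(rectifyNormalize(numeric(0)), "empty")
  expect_error(rectifyNormalize(c(0, 0, 0)), "zero")
  set.seed(2)
  x <- rnorm(500)
  expect_equal(max(rectifyNormalize(x)), 1)
  expect_equal(rectifyNormalize(-x), rectifyNormalize(x))
})

test_that("main frequency finds the dominant non-DC component", {
  fs <- 4000
  t <- seq(0, 20, by = 1 / fs)
  # low-frequency amplitude modulation like the jaw repetition rate
  x <- (0.6 + 0.4 * cos(2 * pi * 2 * t)) * rnorm(length(t))
  rec <- AudioRecord(x / max(abs(x)), fs = fs)
  f0 <- mainFrequency(rec)
  expect_equal(f0, 2, tolerance = 0.101)  # within ~2 bin widths

  # dominant 1 Hz against a weaker 5 Hz rider, checked against a
  # brute-force magnitude scan of the same rectified signal
  y <- abs(sin(2 * pi * 0.5 * t)) + 0.3 * abs(sin(2 * pi * 2.5 * t))
  recY <- AudioRecord(y / max(y) - 0.5, fs = fs)
  fY <- mainFrequency(recY)
  r <- rectifyNormalize(samples(recY))
  spec <- Mod(fft(r))
  freqs <- (seq_along(r) - 1) * fs / length(r)
  keep <- which(freqs >= 0.125 & freqs <= fs / 2)
  expect_equal(fY, freqs[keep[which.max(spec[keep])]])

  expect_error(mainFrequency(AudioRecord(rnorm(100), fs = 4000)),
               "too short")
  # determinism
  rec2 <- AudioRecord(rnorm(fs * 25), fs = fs)
  expect_identical(mainFrequency(rec2), mainFrequency(rec2))
})

test_that("the zero-phase elliptic low-pass honours its design contract", {
  fs <- 4000
  # passband identity at DC
  y <- lowpassElliptic(rep(0.7, 20000), 1, fs)
  expect_lt(max(abs(y - 0.7)), 1e-6)
  # a tone ten times above cutoff is attenuated beyond the stopband spec
  t <- (0:159999) / fs
  x <- 1 + 0.5 * sin(2 * pi * 10 * t)
  yf <- lowpassElliptic(x, 1, fs, attenDb = 40)
  mid <- 40000:120000
  expect_lt(sqrt(mean((yf[mid] - mean(x))^2)),
            10^(-40 / 20) * sqrt(mean((x[mid] - mean(x))^2)))
  expect_true(all(is.finite(yf)))
  expect_length(yf, length(x))
  expect_error(lowpassElliptic(x, 3000, fs), "fs/2")
})

test_that("moving average matches the brute-force clipped-window oracle", {
  expect_equal(movingAverage(c(0, 3, 0), 3)[2], 1)
  expect_equal(movingAverage(rep(2.5, 10), 4), rep(2.5, 10))
  expect_error(movingAverage(1:5, 0), "window")
  set.seed(4)
  for (w in c(1, 2, 7, 16)) {
    x <- rnorm(100)
    expect_equal(movingAverage(x, w), bruteMovingAverage(x, w),
                 tolerance = 1e-12)
  }
})

test_that("emphasis squares, amplifies and preserves peak location", {
  env <- c(0, 1)
  expect_equal(20 * env^2, c(0, 20))       # pre-smoothing values
  expect_equal(emphasize(rep(0, 50), 20, 5), rep(0, 50))
  # argmax of a smoothed unimodal envelope stays near the input argmax
  set.seed(5)
  for (i in 1:10) {
    n <- 400
    peak <- sample(50:350, 1)
    env <- pmax(0, 1 - abs(seq_len(n) - peak) / 200)
    w <- 21
    out <- emphasize(env, 20, w)
    expect_lte(abs(which.max(out) - peak), w)
  }
})

test_that("peak detection matches the greedy-by-height oracle", {
  # two equal peaks far apart are both kept
  env <- c(0, 1, 0, 0, 0, 0, 0, 1, 0)
  expect_equal(detectPeaks(env, 3), c(2L, 8L))
  # of two close peaks only the taller survives
  env2 <- c(0, 1, 0, 2, 0)
  expect_equal(detectPeaks(env2, 3), 4L)
  # a monotone ramp has no interior maximum
  expect_length(detectPeaks(seq(0, 1, length.out = 50), 5), 0)
  # plateau peaks are reported at their first sample
  expect_equal(detectPeaks(c(0, 1, 1, 0), 1), 2L)
  set.seed(6)
  for (i in 1:30) {
    env <- round(runif(sample(10:80, 1)), 2)   # ties are likely
    md <- sample(1:10, 1)
    expect_equal(detectPeaks(env, md), brutePeaks(env, md),
                 info = sprintf("case %d", i))
  }
})

test_that("segment boundaries cross at the documented peak fraction", {
  # symmetric triangular peak of height 1 over samples 1..201 (peak at 101):
  # the 20% crossings sit analytically at 21 and 181
  env <- c(seq(0, 1, length.out = 101), seq(1, 0, length.out = 101)[-1])
  segs <- segmentsFromPeaks(env, 101L, 0.8)
  expect_equal(IRanges::start(segs), 21)
  expect_equal(IRanges::end(segs), 181)
  # a peak at the edge with no down-crossing clips to the signal bounds
  ramp <- seq(0, 1, length.out = 50)
  segs2 <- segmentsFromPeaks(c(ramp, 0.95), 50L, 0.8)
  expect_equal(IRanges::start(segs2), 11)
  expect_equal(IRanges::end(segs2), 51)
  # overlapping extents merge into one segment
  env3 <- c(seq(0, 1, length.out = 50), seq(1, 0.5, length.out = 20),
            seq(0.5, 1, length.out = 20), seq(1, 0, length.out = 50))
  pks <- detectPeaks(env3, 10)
  segs3 <- segmentsFromPeaks(env3, pks, 0.8)
  expect_length(segs3, 1)
  expect_length(segmentsFromPeaks(env3, integer(0), 0.8), 0)
})

test_that("the full DSP chain is deterministic and length-preserving", {
  ann <- generateRecord(syntheticConfig(nRepetitions = 6), seed = 7)
  rec <- audioRecord(ann)
  m1 <- dspSegment(rec)
  m2 <- dspSegment(rec)
  expect_identical(m1, m2)
  expect_length(m1, nSamples(rec))
  expect_equal(length(maskToSegments(m1)), 6)
  expect_gt(diceCoefficient(mask(ann), m1), 0.5)
  expect_error(dspSegment(AudioRecord(rep(0, 1000))), "zero")
})
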