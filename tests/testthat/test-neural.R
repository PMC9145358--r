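test_that("min-absolute pooling equals the brute-force per-window oracle", {
  expect_equal(minAbsPool(c(1, -2, 0.5, 3), 2), c(1, 0.5))
  expect_equal(minAbsPool(c(0, 5), 2), 0)      # zero propagation
  expect_equal(minAbsPool(rep(3, 12), 5), rep(3, 3))
  expect_error(minAbsPool(1:4, 0), "window")
  set.seed(12)
  for (i in 1:100) {
    x <- rnorm(sample(1:60, 1))
    w <- sample(1:8, 1)
    expect_identical(minAbsPool(x, w), bruteMinAbsPool(x, w))
    # the defining identity P(x) = -M(-|x|)
    expect_identical(minAbsPool(x, w), -tmjseg:::.maxPoolVec(-abs(x), w))
  }
})

.colMaxPair <- function(v) sapply(seq(1, length(v), 2),
                                  function(s) max(v[s:(s + 1)]))

test_that("the pooling block doubles channels and halves time", {
  set.seed(13)
  x <- matrix(rnorm(800), 100, 8)
  y <- poolingBlock(x, 2)
  expect_equal(dim(y), c(50, 16))
  # first half is the max-pooled channels, second half min-abs-pooled
  for (c in 1:8) {
    expect_equal(y[, c], .colMaxPair(x[, c]))
    expect_equal(y[, 8 + c], bruteMinAbsPool(x[, c], 2))
  }
  # non-negative input with a zero per window: min-abs half is zero
  z <- matrix(c(0, 3, 0, 7), 4, 1)
  expect_equal(poolingBlock(z, 2), cbind(c(3, 7), c(0, 0)))
})

test_that("the network maps any window to per-sample probabilities", {
  cfg <- tinyModelConfig()
  model <- buildModel(cfg, seed = 3)
  X <- array(rnorm(32 * 2), c(32, 2, 1))
  out <- tmjseg:::.modelForward(model@params, cfg, X)
  expect_equal(dim(out$probs), c(32, 2, 1))
  expect_true(all(out$probs > 0 & out$probs < 1))
  # deterministic forward; weight seed reproducibility
  out2 <- tmjseg:::.modelForward(model@params, cfg, X)
  expect_identical(out$probs, out2$probs)
  m2 <- buildModel(cfg, seed = 3)
  expect_identical(m2@params, model@params)
  m3 <- buildModel(cfg, seed = 4)
  expect_false(identical(m3@params, model@params))
  expect_error(modelConfig(inputLen = 30L, channels = c(2L, 3L),
                           poolWindow = 2L), "divisible")
})

test_that("analytic gradients match finite differences", {
  set.seed(14)
  cfg <- tinyModelConfig()
  model <- buildModel(cfg, seed = 15)
  B <- 2
  X <- array(rnorm(cfg$inputLen * B), c(cfg$inputLen, B, 1))
  Y <- array(rbinom(cfg$inputLen * B, 1, 0.5), c(cfg$inputLen, B, 1))
  lossFn <- function(params)
    tmjseg:::.bceLoss(tmjseg:::.modelForward(params, cfg, X)$probs, Y)
  fw <- tmjseg:::.modelForward(model@params, cfg, X, cache = TRUE)
  grads <- tmjseg:::.modelBackward(model@params, cfg,
                                   (fw$probs - Y) / length(Y), fw$cache)
  g <- flattenParams(grads)
  p0 <- flattenParams(model@params)
  expect_length(g, length(p0))
  eps <- 1e-5
  idx <- sort(sample(length(p0), 50))
  num <- vapply(idx, function(i) {
    vp <- p0; vp[i] <- vp[i] + eps
    vm <- p0; vm[i] <- vm[i] - eps
    (lossFn(rebuildParams(model@params, vp)$x) -
       lossFn(rebuildParams(model@params, vm)$x)) / (2 * eps)
  }, numeric(1))
  # overall agreement (individual coordinates can sit on ReLU/pool kinks
  # where the finite difference itself is ill-defined)
  relerr <- abs(num - g[idx]) / pmax(abs(num) + abs(g[idx]), 1e-6)
  expect_lt(median(relerr), 1e-6)
  expect_lt(sqrt(sum((num - g[idx])^2)) / sqrt(sum(num^2)), 1e-3)
})

test_that("chunked prediction returns a mask of exactly the input length", {
  cfg <- tinyModelConfig()        # inputLen 32
  model <- buildModel(cfg, seed = 5)
  set.seed(16)
  for (n in c(32L, 31L, 33L, 40000L %% 977L, sample(1:500, 6))) {
    rec <- AudioRecord(rnorm(n) / 5, fs = 4000)
    m <- predictMask(model, rec)
    expect_length(m, n)
    expect_true(all(m %in% c(0L, 1L)))
  }
  x <- rnorm(100) / 5
  pr <- predictProbs(model, AudioRecord(x))
  expect_length(pr, 100)
  # threshold ties map to the positive class
  expect_identical(as.integer(pr >= 0.5), predictMask(model, x))
  expect_error(predictMask(model, numeric(0)), "empty")
})

test_that("the learning-rate schedule steps by a tenth every 400 epochs", {
  cfg <- trainConfig()
  expect_equal(learningRateAt(c(0, 400, 800), cfg),
               c(1e-4, 1e-5, 1e-6))
  expect_equal(learningRateAt(399, cfg), 1e-4)
  custom <- trainConfig(lr0 = 0.01, lrDecayFactor = 0.5, lrDecayEvery = 10L)
  expect_equal(learningRateAt(25, custom), 0.01 * 0.25)
})

test_that("random crops align signal and mask and vary across draws", {
  ann <- fastRecord(seed = 17, nRepetitions = 5)
  n <- nSamples(ann)
  cr <- randomCrop(ann, n)            # whole record
  expect_equal(cr$signal, samples(ann))
  set.seed(18)
  starts <- replicate(100, {
    cr <- randomCrop(ann, 4000L)
    i <- which(samples(ann) == cr$signal[1])[1]
    expect_identical(cr$mask, mask(ann)[i:(i + 3999L)])
    i
  })
  expect_gt(length(unique(starts)), 10)
  # short records pad on the right with silence and background label
  short <- AnnotatedRecord(AudioRecord(rnorm(100) / 5), rep(1L, 100))
  cr2 <- randomCrop(short, 150L)
  expect_equal(cr2$signal[101:150], rep(0, 50))
  expect_equal(cr2$mask[101:150], rep(0L, 50))
})

test_that("patient-wise splits never leak a patient across partitions", {
  corpus <- unlist(lapply(1:10, function(p) {
    lapply(1:3, function(k) {
      ann <- fastRecord(seed = p * 10 + k, nRepetitions = 5)
      AnnotatedRecord(AudioRecord(samples(ann), patientId = sprintf("P%02d", p)),
                      mask(ann))
    })
  }), recursive = FALSE)
  sets <- splitPatientwise(corpus, c(train = 0.6, val = 0.2, test = 0.2),
                           seed = 1)
  pids <- lapply(sets, function(s) unique(vapply(s, patientId, character(1))))
  expect_length(pids$train, 6)
  expect_length(pids$val, 2)
  expect_length(pids$test, 2)
  expect_length(Reduce(intersect, pids), 0)
  # all three recordings of a patient travel together
  expect_length(sets$train, 18)
  # determinism
  sets2 <- splitPatientwise(corpus, seed = 1)
  expect_identical(lapply(sets2, length), lapply(sets, length))
  expect_error(splitPatientwise(corpus[1:3][c(1)], c(0.5, 0.3, 0.2)),
               "fewer patients")
})

test_that("a short training run reduces the loss and records history", {
  corpus <- lapply(1:6, function(s) {
    ann <- fastRecord(seed = s, nRepetitions = 5)
    AnnotatedRecord(AudioRecord(samples(ann), patientId = sprintf("P%d", s)),
                    mask(ann))
  })
  cfg <- modelConfig(inputLen = 1024L, channels = c(4L, 6L), kernelSize = 5L,
                     poolWindow = 4L, lstmLayers = 2L, lstmHidden = 8L)
  tcfg <- trainConfig(epochs = 30L, lr0 = 3e-3, batchSize = 2L, seed = 2)
  fit <- trainModel(buildModel(cfg, seed = 2), corpus[1:4], corpus[5:6], tcfg)
  expect_equal(nrow(fit$history), 30)
  expect_equal(fit$history$lr, rep(3e-3, 30))
  # epoch losses ride on the random-crop draw, so compare a tail average
  expect_lt(mean(tail(fit$history$trainLoss, 4)), fit$history$trainLoss[1])
  expect_s4_class(fit$model, "SegmentationModel")
  expect_error(trainModel(buildModel(cfg), list(), corpus[1:2], tcfg),
               "non-empty")
})

test_that("model checkpoints round-trip through save/load", {
  model <- buildModel(tinyModelConfig(), seed = 6)
  path <- withr::local_tempfile(fileext = ".ckpt")
  saveModel(model, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- loadModel(path)
  expect_identical(back@params, model@params)
  x <- rnorm(64) / 5
  expect_identical(predictProbs(back, x), predictProbs(model, x))
})
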