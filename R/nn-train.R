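#' Training configuration
#'
#' Reference protocol: 1200 epochs, initial learning rate `1e-4` decayed
#' by a factor of ten every 400 epochs, one random fixed-length crop of
#' each training example per epoch (so the network never sees the same
#' window twice), per-sample binary cross-entropy loss, Adam updates.
#'
#' @param epochs number of training epochs (default 1200).
#' @param lr0 initial learning rate (default 1e-4).
#' @param lrDecayFactor multiplicative decay (default 0.1).
#' @param lrDecayEvery epochs between decays (default 400).
#' @param cropLen training crop length in samples; `NULL` uses the
#'   model's `inputLen`.
#' @param batchSize examples per Adam update (default 8).
#' @param seed RNG seed applied at the start of training (default 42).
#' @return A validated list of class `tmjTrainConfig`.
#' @export
trainConfig <- function(epochs = 1200L, lr0 = 1e-4, lrDecayFactor = 0.1,
                        lrDecayEvery = 400L, cropLen = NULL,
                        batchSize = 8L, seed = 42L) {
  if (epochs < 1) stop("epochs must be positive")
  if (lr0 <= 0) stop("lr0 must be positive")
  if (lrDecayFactor <= 0 || lrDecayFactor > 1)
    stop("lrDecayFactor must lie in (0, 1]")
  if (lrDecayEvery < 1) stop("lrDecayEvery must be positive")
  if (batchSize < 1) stop("batchSize must be positive")
  structure(list(epochs = as.integer(epochs), lr0 = lr0,
                 lrDecayFactor = lrDecayFactor,
                 lrDecayEvery = as.integer(lrDecayEvery),
                 cropLen = if (is.null(cropLen)) NULL else as.integer(cropLen),
                 batchSize = as.integer(batchSize),
                 seed = as.integer(seed)),
            class = "tmjTrainConfig")
}

#' Learning rate at a given epoch
#'
#' The stepped schedule
#' `lr0 * lrDecayFactor ^ floor(epoch / lrDecayEvery)` with 0-based
#' epochs: under the defaults, epochs 0, 400 and 800 train at 1e-4,
#' 1e-5 and 1e-6.
#'
#' @param epoch 0-based epoch index (vectorized).
#' @param config a [trainConfig()].
#' @return Numeric vector of learning rates.
#' @examples
#' learningRateAt(c(0, 400, 800), trainConfig())
#' @export
learningRateAt <- function(epoch, config = trainConfig()) {
  config$lr0 * config$lrDecayFactor ^ floor(epoch / config$lrDecayEvery)
}

#' Random aligned crop of a labelled record
#'
#' Draws a uniformly random `cropLen`-sample window, identical for signal
#' and mask. Records shorter than `cropLen` are right-padded with zeros
#' (mask padding 0). Used once per training example per epoch as the
#' regularisation that prevents the network from memorising whole
#' recordings.
#'
#' @param annotated an [AnnotatedRecord-class].
#' @param cropLen window length in samples.
#' @return List with numeric `signal` and integer `mask`, both of length
#'   `cropLen`.
#' @export
randomCrop <- function(annotated, cropLen) {
  stopifnot(is(annotated, "AnnotatedRecord"))
  cropLen <- as.integer(cropLen)
  x <- samples(annotated)
  m <- mask(annotated)
  n <- length(x)
  if (n < cropLen) {
    pad <- cropLen - n
    return(list(signal = c(x, numeric(pad)), mask = c(m, integer(pad))))
  }
  start <- sample.int(n - cropLen + 1L, 1L)
  idx <- start:(start + cropLen - 1L)
  list(signal = x[idx], mask = m[idx])
}

#' Patient-wise train/validation/test split
#'
#' Partitions patients (never individual recordings) into the given
#' fractions after a seeded shuffle, so that all recordings of a patient
#' land in exactly one partition and no patient identity leaks between
#' training and evaluation.
#'
#' @param corpus list of [AnnotatedRecord-class] objects carrying
#'   `patientId` metadata.
#' @param fractions numeric vector of partition proportions, normalized
#'   internally; default `c(train = 0.6, val = 0.2, test = 0.2)`.
#' @param seed optional integer seed for the shuffle.
#' @return Named list of sub-corpora, one per fraction (names
#'   `train`/`val`/`test` for the default three-way split).
#' @export
splitPatientwise <- function(corpus, fractions = c(train = 0.6, val = 0.2,
                                                   test = 0.2),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- vapply(corpus, patientId, character(1))
  patients <- unique(ids)
  nP <- length(patients)
  if (nP < length(fractions))
    stop("fewer patients (", nP, ") than partitions (", length(fractions), ")")
  fr <- fractions / sum(fractions)
  shuffled <- sample(patients)
  bounds <- round(cumsum(c(0, fr)) * nP)
  sizes <- diff(bounds)
  assign <- rep(seq_along(fr), sizes)
  out <- lapply(seq_along(fr), function(k) {
    keep <- ids %in% shuffled[assign == k]
    corpus[keep]
  })
  names(out) <- if (!is.null(names(fractions))) names(fractions) else
    paste0("part", seq_along(fr))
  out
}

# stack cropped examples into (T,B,1) arrays
.stackBatch <- function(set, idx, cropLen) {
  B <- length(idx)
  X <- array(0, c(cropLen, B, 1))
  Y <- array(0, c(cropLen, B, 1))
  for (j in seq_along(idx)) {
    cr <- randomCrop(set[[idx[j]]], cropLen)
    X[, j, 1] <- cr$signal
    Y[, j, 1] <- cr$mask
  }
  list(X = X, Y = Y)
}

# deterministic center crops for the validation loss
.centerBatch <- function(set, cropLen) {
  B <- length(set)
  X <- array(0, c(cropLen, B, 1))
  Y <- array(0, c(cropLen, B, 1))
  for (j in seq_len(B)) {
    x <- samples(set[[j]])
    m <- mask(set[[j]])
    n <- length(x)
    if (n < cropLen) {
      x <- c(x, numeric(cropLen - n))
      m <- c(m, integer(cropLen - n))
      n <- cropLen
    }
    start <- (n - cropLen) %/% 2L + 1L
    idx <- start:(start + cropLen - 1L)
    X[, j, 1] <- x[idx]
    Y[, j, 1] <- m[idx]
  }
  list(X = X, Y = Y)
}

.adamInit <- function(params) {
  zero <- function(x) {
    if (is.list(x)) lapply(x, zero) else array(0, dim(x) %||% length(x))
  }
  list(m = zero(params), v = zero(params), t = 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  tt <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(upd, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"),
                  m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^tt)
    vh <- v / (1 - beta2^tt)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  out <- Map(upd, params, grads, state$m, state$v)
  list(params = lapply(out, `[[`, "p"),
       state = list(m = lapply(out, `[[`, "m"),
                    v = lapply(out, `[[`, "v"), t = tt))
}

#' Train the segmentation network
#'
#' Runs the full protocol: per epoch, one fresh random crop of every
#' training example, mini-batch Adam updates of the per-sample binary
#' cross-entropy, and the stepped learning-rate schedule of
#' [learningRateAt()]. The validation loss is computed every epoch on
#' deterministic center crops of the validation records. Fully
#' reproducible under the configuration seed.
#'
#' @param model a [SegmentationModel-class] (typically from
#'   [buildModel()]).
#' @param trainSet,valSet non-empty lists of [AnnotatedRecord-class].
#' @param config a [trainConfig()].
#' @param verbose print a progress line every 10 epochs.
#' @return List with `model` (trained [SegmentationModel-class]) and
#'   `history` (data frame with one row per epoch: `epoch` (0-based),
#'   `lr`, `trainLoss`, `valLoss`).
#' @export
trainModel <- function(model, trainSet, valSet, config = trainConfig(),
                       verbose = FALSE) {
  stopifnot(is(model, "SegmentationModel"))
  if (!inherits(config, "tmjTrainConfig"))
    stop("config must come from trainConfig()")
  if (length(trainSet) == 0L || length(valSet) == 0L)
    stop("training and validation sets must be non-empty")
  set.seed(config$seed)
  cfg <- model@config
  cropLen <- config$cropLen %||% cfg$inputLen
  if (cropLen != cfg$inputLen)
    stop("cropLen must equal the model's inputLen (", cfg$inputLen, ")")
  params <- model@params
  state <- .adamInit(params)
  nTr <- length(trainSet)
  hist <- data.frame(epoch = seq_len(config$epochs) - 1L, lr = NA_real_,
                     trainLoss = NA_real_, valLoss = NA_real_)
  valBatch <- .centerBatch(valSet, cropLen)
  for (e in seq_len(config$epochs)) {
    lr <- learningRateAt(e - 1L, config)
    ord <- sample.int(nTr)
    losses <- numeric(0)
    for (bStart in seq(1L, nTr, by = config$batchSize)) {
      idx <- ord[bStart:min(bStart + config$batchSize - 1L, nTr)]
      ba <- .stackBatch(trainSet, idx, cropLen)
      fw <- .modelForward(params, cfg, ba$X, cache = TRUE)
      losses <- c(losses, .bceLoss(fw$probs, ba$Y))
      dLogits <- (fw$probs - ba$Y) / length(ba$Y)
      grads <- .modelBackward(params, cfg, dLogits, fw$cache)
      st <- .adamStep(params, grads, state, lr)
      params <- st$params
      state <- st$state
    }
    vf <- .modelForward(params, cfg, valBatch$X)
    hist$lr[e] <- lr
    hist$trainLoss[e] <- mean(losses)
    hist$valLoss[e] <- .bceLoss(vf$probs, valBatch$Y)
    if (verbose && (e %% 10 == 0 || e == 1))
      message(sprintf("epoch %4d  lr %.1e  train %.4f  val %.4f",
                      e - 1L, lr, hist$trainLoss[e], hist$valLoss[e]))
  }
  list(model = new("SegmentationModel", config = cfg, params = params),
       history = hist)
}
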