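#' Min-absolute pooling
#'
#' The pooling operator \eqn{P(x) = -M(-|x|)} where \eqn{M} is max
#' pooling: per window, the magnitude of the element closest to zero.
#' Standard max pooling discards small values, yet in an auscultation
#' signal the near-silent samples between episodes are informative; this
#' operator propagates them through the encoder. A trailing window
#' shorter than `window` is pooled over the available samples (shrinking
#' window), so the output length is `ceiling(n / window)`.
#'
#' @param x numeric vector, or a time-by-channels matrix (pooled per
#'   column).
#' @param window pool window (>= 1).
#' @return Pooled vector (or matrix) of length `ceiling(n / window)`.
#' @examples
#' minAbsPool(c(1, -2, 0.5, 3), 2)  # 1, 0.5
#' @export
minAbsPool <- function(x, window) {
  window <- as.integer(window)
  if (is.na(window) || window < 1L) stop("window must be >= 1")
  if (is.matrix(x))
    return(apply(x, 2, minAbsPool, window = window))
  x <- as.numeric(x)
  grp <- (seq_along(x) - 1L) %/% window
  as.vector(tapply(abs(x), grp, min))
}

# plain max pooling with the same shrinking-window rule (internal helper,
# shared by poolingBlock and used to cross-check the P(x) = -M(-|x|) form)
.maxPoolVec <- function(x, window) {
  if (is.matrix(x))
    return(apply(x, 2, .maxPoolVec, window = window))
  x <- as.numeric(x)
  grp <- (seq_along(x) - 1L) %/% window
  as.vector(tapply(x, grp, max))
}

#' Parallel max / min-absolute pooling block
#'
#' The encoder pooling stage: max pooling and min-absolute pooling are
#' applied in parallel and their outputs concatenated along the channel
#' dimension, so the channel count doubles while the temporal length
#' shrinks by `window`. Columns `1..C` of the result are the max-pooled
#' channels, columns `C+1..2C` the min-absolute-pooled ones.
#'
#' @param x time-by-channels numeric matrix (a vector is treated as one
#'   channel).
#' @param window pool window (>= 1).
#' @return Matrix of dimension `ceiling(T / window)` by `2 * C`.
#' @export
poolingBlock <- function(x, window) {
  if (!is.matrix(x)) x <- matrix(as.numeric(x), ncol = 1)
  mx <- .maxPoolVec(x, window)
  mn <- minAbsPool(x, window)
  if (!is.matrix(mx)) { mx <- matrix(mx, ncol = ncol(x)); mn <- matrix(mn, ncol = ncol(x)) }
  cbind(mx, mn)
}

#' Architecture configuration of the segmentation network
#'
#' The reference architecture has two convolutional blocks (two
#' convolutional layers each, followed by the parallel max/min-absolute
#' pooling stage) and three LSTM layers in the bottleneck; the decoder
#' mirrors the encoder with zero-insertion up-sampling, learned
#' convolutions and U-Net skip connections. Channel counts, kernel size
#' and hidden size are tunable; the defaults give a small CPU-trainable
#' model.
#'
#' @param inputLen samples per network input window (default 16000).
#' @param channels integer vector of filters per convolutional block,
#'   one entry per block (default `c(16, 32)`; length fixes the number of
#'   blocks, default 2 as in the reference design).
#' @param kernelSize convolution kernel length in samples, odd
#'   (default 9).
#' @param poolWindow temporal decimation factor per block (default 2).
#' @param lstmLayers number of stacked LSTM layers (default 3).
#' @param lstmHidden LSTM state size (default 64).
#' @return A validated list of class `tmjModelConfig`.
#' @seealso [buildModel()]
#' @export
modelConfig <- function(inputLen = 16000L, channels = c(16L, 32L),
                        kernelSize = 9L, poolWindow = 2L,
                        lstmLayers = 3L, lstmHidden = 64L) {
  inputLen <- as.integer(inputLen)
  channels <- as.integer(channels)
  if (inputLen < 1L) stop("inputLen must be positive")
  if (length(channels) < 1L || any(channels < 1L))
    stop("channels must be a vector of positive filter counts")
  if (kernelSize %% 2 != 1 || kernelSize < 1)
    stop("kernelSize must be odd and positive")
  if (poolWindow < 1L) stop("poolWindow must be >= 1")
  if (lstmLayers < 1L || lstmHidden < 1L)
    stop("lstmLayers and lstmHidden must be positive")
  dec <- as.integer(poolWindow)^length(channels)
  if (inputLen %% dec != 0L)
    stop("inputLen must be divisible by poolWindow^<number of blocks> (",
         dec, ") so the decoder can restore the input length")
  structure(list(inputLen = inputLen, channels = channels,
                 kernelSize = as.integer(kernelSize),
                 poolWindow = as.integer(poolWindow),
                 lstmLayers = as.integer(lstmLayers),
                 lstmHidden = as.integer(lstmHidden)),
            class = "tmjModelConfig")
}

.initConv <- function(k, cin, cout) {
  list(W = matrix(rnorm(k * cin * cout, sd = sqrt(2 / (k * cin))),
                  k * cin, cout),
       b = numeric(cout))
}

.initLstm <- function(cin, h) {
  s <- 1 / sqrt(h)
  b <- numeric(4 * h)
  b[h + seq_len(h)] <- 1    # forget-gate bias starts open
  list(Wx = matrix(runif(cin * 4 * h, -s, s), cin, 4 * h),
       Wh = matrix(runif(h * 4 * h, -s, s), h, 4 * h),
       b = b)
}

#' Build an untrained segmentation network
#'
#' Allocates and initializes all parameter tensors (He-scaled normal for
#' convolutions, uniform \eqn{\pm 1/\sqrt{H}} for LSTM weights with the
#' forget-gate bias opened at 1). Weight initialization draws from R's
#' RNG, so a fixed `seed` gives reproducible weights.
#'
#' @param config a [modelConfig()].
#' @param seed optional integer; seeds the RNG before initialization.
#' @return A [SegmentationModel-class].
#' @export
buildModel <- function(config = modelConfig(), seed = NULL) {
  if (!inherits(config, "tmjModelConfig"))
    stop("config must come from modelConfig()")
  if (!is.null(seed)) set.seed(seed)
  ch <- config$channels
  nB <- length(ch)
  k <- config$kernelSize
  H <- config$lstmHidden
  params <- list(enc = list(), lstm = list(), dec = list())
  cin <- 1L
  for (i in seq_len(nB)) {
    params$enc[[i]] <- list(conv1 = .initConv(k, cin, ch[i]),
                            conv2 = .initConv(k, ch[i], ch[i]))
    cin <- 2L * ch[i]                  # pooling block doubles channels
  }
  lin <- cin
  for (l in seq_len(config$lstmLayers)) {
    params$lstm[[l]] <- .initLstm(lin, H)
    lin <- H
  }
  up <- H
  for (i in nB:1) {
    params$dec[[i]] <- list(
      up = .initConv(k, up, ch[i]),
      conv1 = .initConv(k, 2L * ch[i], ch[i]),
      conv2 = .initConv(k, ch[i], ch[i]))
    up <- ch[i]
  }
  params$out <- .initConv(1L, ch[1], 1L)
  new("SegmentationModel", config = unclass(config), params = params)
}

# full forward pass; X (T,B,1). Returns probabilities and, when cache=TRUE,
# every intermediate needed by .modelBackward.
.modelForward <- function(params, cfg, X, cache = FALSE) {
  p <- cfg$poolWindow
  nB <- length(cfg$channels)
  cc <- list(enc = vector("list", nB), dec = vector("list", nB))
  A <- X
  for (i in seq_len(nB)) {
    c1 <- .convForward(A, params$enc[[i]]$conv1$W, params$enc[[i]]$conv1$b, cache)
    r1 <- pmax(c1$Y, 0)
    c2 <- .convForward(r1, params$enc[[i]]$conv2$W, params$enc[[i]]$conv2$b, cache)
    r2 <- pmax(c2$Y, 0)                 # skip connection source
    pb <- .poolBlockForward(r2, p)
    if (cache)
      cc$enc[[i]] <- list(c1 = c1, z1 = c1$Y, c2 = c2, z2 = c2$Y, pb = pb,
                          skip = r2)
    else cc$enc[[i]] <- list(skip = r2)
    A <- pb$Y
  }
  lcache <- vector("list", length(params$lstm))
  for (l in seq_along(params$lstm)) {
    lf <- .lstmForward(A, params$lstm[[l]]$Wx, params$lstm[[l]]$Wh,
                       params$lstm[[l]]$b, cache)
    lcache[[l]] <- lf
    A <- lf$Y
  }
  cc$lstm <- lcache
  for (i in rev(seq_len(nB))) {
    uz <- .upsampleForward(A, p)
    cu <- .convForward(uz, params$dec[[i]]$up$W, params$dec[[i]]$up$b, cache)
    ru <- pmax(cu$Y, 0)
    skip <- cc$enc[[i]]$skip
    cat_ <- array(c(ru, skip), c(dim(ru)[1], dim(ru)[2],
                                 dim(ru)[3] + dim(skip)[3]))
    c1 <- .convForward(cat_, params$dec[[i]]$conv1$W, params$dec[[i]]$conv1$b, cache)
    r1 <- pmax(c1$Y, 0)
    c2 <- .convForward(r1, params$dec[[i]]$conv2$W, params$dec[[i]]$conv2$b, cache)
    r2 <- pmax(c2$Y, 0)
    if (cache)
      cc$dec[[i]] <- list(cu = cu, zu = cu$Y, c1 = c1, z1 = c1$Y,
                          c2 = c2, z2 = c2$Y, nUp = dim(ru)[3])
    A <- r2
  }
  co <- .convForward(A, params$out$W, params$out$b, cache)
  probs <- .sigmoid(co$Y)
  if (cache) {
    cc$out <- co
    cc$zOut <- co$Y
    list(probs = probs, cache = cc)
  } else list(probs = probs)
}

# backward pass from d(loss)/d(logits); returns gradients shaped like params
.modelBackward <- function(params, cfg, dLogits, cc) {
  p <- cfg$poolWindow
  nB <- length(cfg$channels)
  g <- list(enc = vector("list", nB), lstm = vector("list", length(params$lstm)),
            dec = vector("list", nB))
  bo <- .convBackward(dLogits, params$out$W, cc$out)
  g$out <- list(W = bo$dW, b = bo$db)
  dA <- bo$dX
  for (i in seq_len(nB)) {
    dc <- cc$dec[[i]]
    dr2 <- dA * (dc$z2 > 0)
    b2 <- .convBackward(dr2, params$dec[[i]]$conv2$W, dc$c2)
    dr1 <- b2$dX * (dc$z1 > 0)
    b1 <- .convBackward(dr1, params$dec[[i]]$conv1$W, dc$c1)
    nUp <- dc$nUp
    dru <- b1$dX[, , seq_len(nUp), drop = FALSE]
    dskip <- b1$dX[, , nUp + seq_len(dim(b1$dX)[3] - nUp), drop = FALSE]
    g$enc[[i]]$dskip <- dskip           # re-injected on the way up
    druz <- dru * (dc$zu > 0)
    bu <- .convBackward(druz, params$dec[[i]]$up$W, dc$cu)
    g$dec[[i]] <- list(up = list(W = bu$dW, b = bu$db),
                       conv1 = list(W = b1$dW, b = b1$db),
                       conv2 = list(W = b2$dW, b = b2$db))
    dA <- .upsampleBackward(bu$dX, p)
  }
  for (l in rev(seq_along(params$lstm))) {
    bl <- .lstmBackward(dA, params$lstm[[l]]$Wx, params$lstm[[l]]$Wh,
                        cc$lstm[[l]])
    g$lstm[[l]] <- list(Wx = bl$dWx, Wh = bl$dWh, b = bl$db)
    dA <- bl$dX
  }
  for (i in rev(seq_len(nB))) {
    ec <- cc$enc[[i]]
    dr2 <- .poolBlockBackward(dA, ec$pb, p) + g$enc[[i]]$dskip
    dr2 <- dr2 * (ec$z2 > 0)
    b2 <- .convBackward(dr2, params$enc[[i]]$conv2$W, ec$c2)
    dr1 <- b2$dX * (ec$z1 > 0)
    b1 <- .convBackward(dr1, params$enc[[i]]$conv1$W, ec$c1)
    g$enc[[i]] <- list(conv1 = list(W = b1$dW, b = b1$db),
                       conv2 = list(W = b2$dW, b = b2$db))
    dA <- b1$dX
  }
  g
}

# mean binary cross-entropy of probabilities vs 0/1 targets
.bceLoss <- function(probs, Y) {
  eps <- 1e-12
  -mean(Y * log(probs + eps) + (1 - Y) * log(1 - probs + eps))
}

#' Predict a segment mask for a whole recording
#'
#' The network consumes fixed-length windows, so the signal is split into
#' consecutive non-overlapping `inputLen`-sample chunks which are fed
#' through the network as one batch; a final short chunk is zero-padded
#' and the padded tail of its prediction discarded. Per-sample
#' probabilities at or above `threshold` (default 0.5; ties map to the
#' positive class) become label 1.
#'
#' @param model a trained [SegmentationModel-class].
#' @param record an [AudioRecord-class] (or numeric signal vector).
#' @param threshold decision threshold on the per-sample probability.
#' @return Integer 0/1 mask of exactly the input length.
#' @export
predictMask <- function(model, record, threshold = 0.5) {
  p <- predictProbs(model, record)
  as.integer(p >= threshold)
}

#' Per-sample segment probabilities for a whole recording
#'
#' Chunked inference as in [predictMask()], returning the raw sigmoid
#' probabilities instead of thresholded labels.
#'
#' @inheritParams predictMask
#' @return Numeric vector of probabilities in \eqn{[0, 1]}, one per sample.
#' @export
predictProbs <- function(model, record) {
  stopifnot(is(model, "SegmentationModel"))
  x <- if (is(record, "AudioRecord")) record@samples else as.numeric(record)
  n <- length(x)
  if (n == 0L) stop("empty signal")
  L <- model@config$inputLen
  nCh <- ceiling(n / L)
  xp <- c(x, numeric(nCh * L - n))
  X <- array(xp, c(L, nCh, 1))        # chunks ride the batch axis
  out <- .modelForward(model@params, model@config, X)
  pr <- out$probs
  dim(pr) <- NULL
  pr[seq_len(n)]
}

#' Save / load a segmentation model checkpoint
#'
#' `saveModel()` serializes the weights to `path` (an RDS container) and
#' writes a human-readable JSON sidecar `<path>.json` with the
#' architecture configuration. `loadModel()` restores the model.
#'
#' @param model a [SegmentationModel-class].
#' @param path checkpoint file path.
#' @return `saveModel()` returns `path` invisibly; `loadModel()` the
#'   restored [SegmentationModel-class].
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "SegmentationModel"))
  saveRDS(list(config = model@config, params = model@params), path)
  jsonlite::write_json(model@config, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  obj <- readRDS(path)
  new("SegmentationModel", config = obj$config, params = obj$params)
}
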