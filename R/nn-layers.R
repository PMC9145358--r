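# Low-level differentiable layers for the 1D U-Net/LSTM segmenter.
#
# Activations are arrays of dim (T, B, C): time, batch, channels. Time is
# the leading (fastest-varying) dimension so that contiguous time slices
# reshape to (T*B, C) matrices without copying, which keeps the
# convolutions as single BLAS calls. All backward functions consume the
# cache produced by their forward counterpart and return gradients of the
# same shapes as their inputs.

.sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- 1D convolution, 'same' padding, odd kernel ----------------------------

# gather-index cache for im2col (keyed by shape; a handful of shapes live
# at any time)
.convIdxCache <- new.env(parent = emptyenv())

.convGatherIdx <- function(Tn, B, Cin, k) {
  key <- paste(Tn, B, Cin, k, sep = "x")
  hit <- .convIdxCache[[key]]
  if (!is.null(hit)) return(hit)
  Tp <- Tn + k - 1
  base <- rep_len(seq_len(Tn), Tn * B) +
    rep(seq_len(B) - 1L, each = Tn) * Tp
  colOff <- rep(0:(k - 1), each = Cin) +
    rep((0:(Cin - 1)) * (Tp * B), times = k)
  idx <- rep(base, times = k * Cin) +
    rep(colOff, each = Tn * B)
  if (length(ls(.convIdxCache)) > 64) rm(list = ls(.convIdxCache),
                                         envir = .convIdxCache)
  .convIdxCache[[key]] <- idx
  idx
}

.convForward <- function(X, W, b, cache = FALSE) {
  d <- dim(X)
  Tn <- d[1]; B <- d[2]; Cin <- d[3]
  k <- nrow(W) / Cin
  Cout <- ncol(W)
  if (k != round(k)) stop("kernel/channel mismatch in conv weights")
  pad <- (k - 1) / 2
  if (pad != round(pad)) stop("conv kernel size must be odd")
  if (k == 1L) {
    Xcol <- X
    dim(Xcol) <- c(Tn * B, Cin)
  } else {
    Xpad <- array(0, c(Tn + k - 1, B, Cin))
    Xpad[pad + seq_len(Tn), , ] <- X
    Xcol <- Xpad[.convGatherIdx(Tn, B, Cin, k)]
    dim(Xcol) <- c(Tn * B, k * Cin)
  }
  Y <- Xcol %*% W
  Y <- Y + rep(b, each = Tn * B)
  dim(Y) <- c(Tn, B, Cout)
  if (cache) list(Y = Y, Xcol = Xcol, dims = d) else list(Y = Y)
}

# data gradient of 'same' convolution = convolution of dY with the
# kernel-flipped, channel-transposed weights
.convFlipW <- function(W, k, Cin) {
  Cout <- ncol(W)
  Wb <- array(W, c(Cin, k, Cout))        # (cin, tap, cout)
  Wb <- Wb[, k:1, , drop = FALSE]        # flip taps
  Wb <- aperm(Wb, c(3, 2, 1))            # (cout, tap, cin)
  dim(Wb) <- c(Cout * k, Cin)
  Wb
}

.convBackward <- function(dY, W, fw) {
  d <- fw$dims
  Tn <- d[1]; B <- d[2]; Cin <- d[3]
  k <- nrow(W) / Cin
  Cout <- ncol(W)
  dYm <- dY
  dim(dYm) <- c(Tn * B, Cout)
  dW <- crossprod(fw$Xcol, dYm)
  db <- colSums(dYm)
  if (k == 1L) {
    dX <- tcrossprod(dYm, W)
    dim(dX) <- c(Tn, B, Cin)
  } else {
    dim(dY) <- c(Tn, B, Cout)
    dX <- .convForward(dY, .convFlipW(W, k, Cin), numeric(Cin))$Y
  }
  list(dX = dX, dW = dW, db = db)
}

# ---- pooling ---------------------------------------------------------------

.poolSlices <- function(X, p) {
  Tn <- dim(X)[1]
  lapply(seq_len(p), function(o) {
    s <- X[seq(o, Tn, by = p), , , drop = FALSE]
    s
  })
}

# parallel max pooling / min-absolute pooling, concatenated on channels
.poolBlockForward <- function(X, p) {
  d <- dim(X)
  if (d[1] %% p != 0)
    stop("time length not divisible by the pool window")
  sl <- .poolSlices(X, p)
  Ymax <- Reduce(pmax, sl)
  A <- abs(X)
  slA <- .poolSlices(A, p)
  Ymin <- Reduce(pmin, slA)
  Y <- array(c(Ymax, Ymin), c(d[1] / p, d[2], 2 * d[3]))
  list(Y = Y, X = X, Ymax = Ymax, Ymin = Ymin)
}

.poolBlockBackward <- function(dY, fw, p) {
  d <- dim(fw$X)
  Tp <- d[1] / p; B <- d[2]; C <- d[3]
  dYmax <- dY[, , seq_len(C), drop = FALSE]
  dYmin <- dY[, , C + seq_len(C), drop = FALSE]
  dX <- array(0, d)
  remMax <- array(TRUE, c(Tp, B, C))
  remMin <- array(TRUE, c(Tp, B, C))
  A <- abs(fw$X)
  sg <- sign(fw$X)
  for (o in seq_len(p)) {
    idx <- seq(o, d[1], by = p)
    s <- fw$X[idx, , , drop = FALSE]
    selMax <- (s == fw$Ymax) & remMax
    remMax <- remMax & !selMax
    sA <- A[idx, , , drop = FALSE]
    selMin <- (sA == fw$Ymin) & remMin
    remMin <- remMin & !selMin
    dX[idx, , ] <- dYmax * selMax +
      dYmin * selMin * sg[idx, , , drop = FALSE]
  }
  dX
}

# ---- zero-insertion up-sampling -------------------------------------------

.upsampleForward <- function(X, p) {
  d <- dim(X)
  Y <- array(0, c(d[1] * p, d[2], d[3]))
  Y[seq(1, d[1] * p, by = p), , ] <- X
  Y
}

.upsampleBackward <- function(dY, p) {
  Tn <- dim(dY)[1] / p
  dX <- dY[seq(1, dim(dY)[1], by = p), , , drop = FALSE]
  dim(dX) <- c(Tn, dim(dY)[2], dim(dY)[3])
  dX
}

# ---- LSTM layer ------------------------------------------------------------

# X (T,B,Cin); Wx (Cin,4H), Wh (H,4H), b (4H); gate order i, f, g, o.
.lstmForward <- function(X, Wx, Wh, b, cache = FALSE) {
  d <- dim(X)
  Tn <- d[1]; B <- d[2]; Cin <- d[3]
  H <- ncol(Wx) / 4
  Hout <- array(0, c(Tn, B, H))
  if (cache) {
    Gi <- Gf <- Gg <- Go <- Cs <- Tc <- array(0, c(Tn, B, H))
  }
  h <- matrix(0, B, H)
  cc <- matrix(0, B, H)
  bm <- rep(b, each = B)
  for (t in seq_len(Tn)) {
    Xt <- X[t, , , drop = FALSE]
    dim(Xt) <- c(B, Cin)
    Z <- Xt %*% Wx + h %*% Wh + bm
    i <- .sigmoid(Z[, seq_len(H), drop = FALSE])
    f <- .sigmoid(Z[, H + seq_len(H), drop = FALSE])
    g <- tanh(Z[, 2 * H + seq_len(H), drop = FALSE])
    o <- .sigmoid(Z[, 3 * H + seq_len(H), drop = FALSE])
    cc <- f * cc + i * g
    tc <- tanh(cc)
    h <- o * tc
    Hout[t, , ] <- h
    if (cache) {
      Gi[t, , ] <- i; Gf[t, , ] <- f; Gg[t, , ] <- g; Go[t, , ] <- o
      Cs[t, , ] <- cc; Tc[t, , ] <- tc
    }
  }
  if (cache)
    list(Y = Hout, X = X, Gi = Gi, Gf = Gf, Gg = Gg, Go = Go,
         Cs = Cs, Tc = Tc)
  else list(Y = Hout)
}

.lstmBackward <- function(dY, Wx, Wh, fw) {
  d <- dim(fw$X)
  Tn <- d[1]; B <- d[2]; Cin <- d[3]
  H <- ncol(Wx) / 4
  dWx <- matrix(0, Cin, 4 * H)
  dWh <- matrix(0, H, 4 * H)
  db <- numeric(4 * H)
  dX <- array(0, d)
  dhCarry <- matrix(0, B, H)
  dcCarry <- matrix(0, B, H)
  slice2 <- function(A, t, nc) { s <- A[t, , , drop = FALSE]; dim(s) <- c(B, nc); s }
  for (t in Tn:1) {
    dh <- slice2(dY, t, H) + dhCarry
    i <- slice2(fw$Gi, t, H); f <- slice2(fw$Gf, t, H)
    g <- slice2(fw$Gg, t, H); o <- slice2(fw$Go, t, H)
    tc <- slice2(fw$Tc, t, H)
    do_ <- dh * tc
    dc <- dcCarry + dh * o * (1 - tc^2)
    cPrev <- if (t > 1) slice2(fw$Cs, t - 1, H) else matrix(0, B, H)
    di <- dc * g
    df <- dc * cPrev
    dg <- dc * i
    dcCarry <- dc * f
    dZ <- cbind(di * i * (1 - i), df * f * (1 - f),
                dg * (1 - g^2), do_ * o * (1 - o))
    Xt <- slice2(fw$X, t, Cin)
    hPrev <- if (t > 1) slice2(fw$Y, t - 1, H) else matrix(0, B, H)
    dWx <- dWx + crossprod(Xt, dZ)
    dWh <- dWh + crossprod(hPrev, dZ)
    db <- db + colSums(dZ)
    dX[t, , ] <- dZ %*% t(Wx)
    dhCarry <- dZ %*% t(Wh)
  }
  list(dX = dX, dWx = dWx, dWh = dWh, db = db)
}
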