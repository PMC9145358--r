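#' Configuration of the DSP segmentation pipeline
#'
#' Parameters of the deterministic envelope/peak segmenter: rectify and
#' peak-normalize, low-pass with an elliptic IIR filter whose cutoff is
#' recomputed per signal as the main harmonic of the rectified signal,
#' smooth with a centered moving average, emphasize local maxima by
#' squaring/amplifying/re-smoothing, detect envelope peaks with a
#' main-frequency-derived minimum distance, and place each episode
#' boundary where the envelope falls below a fraction of its peak.
#'
#' @param maWindowSamples moving-average window width in samples
#'   (default 5000, i.e. 1.25 s at 4 kHz).
#' @param gain emphasis multiplier applied to the squared envelope
#'   (default 20).
#' @param boundaryFraction fraction of each peak's amplitude enclosed by
#'   its segment (default 0.8: the segment spans the top 80\% of the peak,
#'   bounded where the envelope drops below 20\% of the peak height).
#' @param filterOrder elliptic low-pass order (default 2; see
#'   [lowpassElliptic()] for why higher orders misbehave at the sub-Hz
#'   adaptive cutoffs this pipeline produces).
#' @param passbandRippleDb,stopbandAttenDb elliptic design parameters
#'   (defaults 0.5 dB and 40 dB).
#' @param fminHz lower bound of the main-frequency search in Hz (default
#'   0.125: excludes the large DC component of the rectified signal while
#'   requiring only 16 s of signal — two full cycles — and staying well
#'   below any plausible jaw repetition rate).
#' @param maWindow2Samples window of the second-stage moving-average
#'   smoothing inside [emphasize()] (default 1000 samples, 0.25 s at
#'   4 kHz: wide enough to remove local fluctuation around each envelope
#'   maximum, short enough not to smear episode boundaries further).
#' @return A validated list of class `tmjDspConfig`.
#' @seealso [dspSegment()]
#' @export
dspConfig <- function(maWindowSamples = 5000L, gain = 20,
                      boundaryFraction = 0.8, filterOrder = 2L,
                      passbandRippleDb = 0.5, stopbandAttenDb = 40,
                      fminHz = 0.125, maWindow2Samples = 1000L) {
  if (maWindowSamples < 1) stop("maWindowSamples must be >= 1")
  if (maWindow2Samples < 1) stop("maWindow2Samples must be >= 1")
  if (gain <= 0) stop("gain must be positive")
  if (boundaryFraction <= 0 || boundaryFraction >= 1)
    stop("boundaryFraction must lie strictly between 0 and 1")
  if (filterOrder < 1) stop("filterOrder must be >= 1")
  if (fminHz <= 0) stop("fminHz must be positive")
  structure(list(maWindowSamples = as.integer(maWindowSamples), gain = gain,
                 boundaryFraction = boundaryFraction,
                 filterOrder = as.integer(filterOrder),
                 passbandRippleDb = passbandRippleDb,
                 stopbandAttenDb = stopbandAttenDb, fminHz = fminHz,
                 maWindow2Samples = as.integer(maWindow2Samples)),
            class = "tmjDspConfig")
}

#' Rectify and peak-normalize a signal
#'
#' First pipeline stage: `|x| / max(|x|)`, an amplitude envelope precursor
#' whose peak is exactly 1. Because normalization comes first, the whole
#' pipeline is invariant to overall amplitude scaling of the input.
#'
#' @param record an [AudioRecord-class] or numeric vector.
#' @return Non-negative numeric vector of the input length, max exactly 1.
#' @export
rectifyNormalize <- function(record) {
  x <- if (is(record, "AudioRecord")) record@samples else as.numeric(record)
  if (length(x) == 0L) stop("empty signal")
  a <- abs(x)
  m <- max(a)
  if (m == 0) stop("all-zero signal cannot be normalized")
  a / m
}

#' Main frequency of a signal
#'
#' The frequency bin with maximal discrete-Fourier-transform magnitude of
#' the rectified, peak-normalized signal, excluding DC and all bins below
#' `fminHz`. For a recording of periodic jaw movements this picks up the
#' repetition rate, which then sets both the adaptive low-pass cutoff and
#' the minimum peak distance.
#'
#' @param record an [AudioRecord-class], or a numeric vector (then `fs`
#'   must be given).
#' @param fminHz lower bound of the search in Hz.
#' @param fs sampling rate in Hz when `record` is a plain vector.
#' @return Frequency in Hz of the strongest spectral component.
#' @export
mainFrequency <- function(record, fminHz = 0.125, fs = NULL) {
  if (is(record, "AudioRecord")) {
    fs <- record@fs
    x <- record@samples
  } else {
    if (is.null(fs)) stop("fs must be supplied for a plain numeric signal")
    x <- as.numeric(record)
  }
  n <- length(x)
  if (n / fs < 2 / fminHz)
    stop("signal too short: need at least two cycles of fminHz (",
         sprintf("%.2f", 2 / fminHz), " s)")
  r <- rectifyNormalize(x)
  spec <- Mod(fft(r))
  freqs <- (seq_len(n) - 1) * fs / n
  keep <- freqs >= fminHz & freqs <= fs / 2
  if (!any(keep)) stop("no frequency bins in the search range")
  cand <- which(keep)
  freqs[cand[which.max(spec[cand])]]
}

# Elliptic low-pass as second-order sections in zero-pole-gain form.
# The adaptive cutoff sits orders of magnitude below Nyquist (sub-Hz at
# fs = 4 kHz), where a single direct-form transfer function is numerically
# unusable: its denominator roots cluster at z = 1 and the partial-fraction
# transient amplitudes reach ~1e12 of the signal scale. Designing in
# zero-pole-gain form (analog elliptic prototype, low-pass transform,
# bilinear map, all on roots) and pairing conjugate roots into biquads
# keeps every coefficient well conditioned. Each section is normalized to
# unit DC gain.
.ellipSos <- function(order, rippleDb, attenDb, wn) {
  ncauer <- utils::getFromNamespace("ncauer", "signal")
  Tb <- 2
  W <- 2 / Tb * tan(pi * wn / 2)
  zpg <- ncauer(rippleDb, attenDb, order)
  zpg <- signal::sftrans(zpg, W = W, stop = FALSE)
  zpg <- signal::bilinear(zpg, T = Tb)
  z <- zpg$zero
  p <- zpg$pole
  if (any(Mod(p) >= 1))
    stop("unstable filter design at this cutoff/order; reduce the order")
  pairUp <- function(r) {
    # conjugate pairs (by ascending |Im|); a leftover real root forms a
    # first-order section
    r <- r[order(abs(Im(r)), Re(r))]
    secs <- list()
    while (length(r) > 0) {
      if (abs(Im(r[1])) < 1e-12) {
        secs[[length(secs) + 1L]] <- c(1, -Re(r[1]))
        r <- r[-1]
      } else {
        secs[[length(secs) + 1L]] <- c(1, -2 * Re(r[1]), Mod(r[1])^2)
        r <- r[-(1:2)]
      }
    }
    secs
  }
  bs <- pairUp(z)
  as <- pairUp(p)
  if (length(bs) < length(as))        # pad with pass-through numerators
    bs <- c(bs, rep(list(1), length(as) - length(bs)))
  Map(function(b, a) {
    list(b = b * (sum(a) / sum(b)), a = a)   # unit DC gain per section
  }, bs, as)
}

# one causal pass of a biquad cascade, started in the steady state of the
# level `initVal` (so an input constant at that level maps to itself
# exactly, and the start-up transient scales with the deviation from it)
.sosPass <- function(x, sos, initVal = x[1]) {
  for (s in sos) {
    nb <- length(s$b)
    v <- stats::filter(x, s$b, method = "convolution", sides = 1)
    v[seq_len(nb - 1)] <- initVal * sum(s$b)   # constant-history start
    if (length(s$a) > 1) {
      x <- stats::filter(v, -s$a[-1], method = "recursive",
                         init = rep(initVal, length(s$a) - 1))
    } else x <- v
    x <- as.numeric(x)
  }
  x
}

#' Zero-phase elliptic low-pass filter
#'
#' Applies an elliptic IIR low-pass forward and backward (zero phase, so
#' envelope peaks are not delayed) with the given cutoff. The filter is
#' realized as a cascade of second-order sections designed in
#' zero-pole-gain form, each normalized to unit DC gain and started in
#' steady state — necessary for numerical stability because the adaptive
#' cutoff from [mainFrequency()] is typically a tiny fraction of the
#' Nyquist frequency. A constant therefore passes unchanged, and a
#' stopband tone is attenuated by at least the design attenuation twice
#' (once per direction). Negative excursions from filter ringing are
#' clamped to zero because the result feeds an amplitude envelope.
#'
#' @param env non-negative numeric vector (a rectified signal).
#' @param cutoffHz low-pass cutoff in Hz, must be below `fs / 2`.
#' @param fs sampling rate in Hz.
#' @param order,rippleDb,attenDb elliptic design parameters. The default
#'   order is 2: at cutoffs thousands of times below Nyquist, higher
#'   orders place resonant pole pairs so close to the unit circle that
#'   their ringing (tens of seconds long) swamps the envelope.
#' @return Filtered non-negative vector of the input length.
#' @export
lowpassElliptic <- function(env, cutoffHz, fs, order = 2L, rippleDb = 0.5,
                            attenDb = 40) {
  env <- as.numeric(env)
  if (length(env) == 0L) stop("empty signal")
  if (cutoffHz <= 0 || cutoffHz >= fs / 2)
    stop("cutoffHz must lie strictly between 0 and fs/2")
  sos <- .ellipSos(order, rippleDb, attenDb, 2 * cutoffHz / fs)
  m <- mean(env)
  y <- rev(.sosPass(rev(.sosPass(env, sos, m)), sos, m))
  pmax(y, 0)
}

#' Centered moving average with shrinking edge windows
#'
#' Replaces every sample by the mean over a centered window of
#' `window` samples; near the boundaries the window shrinks to the
#' available samples, so the output length equals the input length. For
#' even windows the extra sample is taken from the left
#' (`floor(window / 2)` left, the remainder right).
#'
#' @param env numeric vector.
#' @param window window width in samples (>= 1).
#' @return Numeric vector of the input length.
#' @export
movingAverage <- function(env, window) {
  env <- as.numeric(env)
  window <- as.integer(window)
  if (is.na(window) || window < 1L) stop("window must be >= 1")
  n <- length(env)
  left <- window %/% 2L
  right <- window - 1L - left
  cs <- c(0, cumsum(env))
  i <- seq_len(n)
  lo <- pmax(1L, i - left)
  hi <- pmin(n, i + right)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Emphasize envelope maxima
#'
#' Squares the envelope, amplifies it (default twenty-fold) and smooths
#' the result with a second moving average to remove local fluctuations.
#' Squaring is a monotone transform of the non-negative envelope, so peak
#' ordering is preserved while low-level fluctuations are suppressed.
#'
#' @param env non-negative numeric vector.
#' @param gain amplification factor (default 20).
#' @param window second-stage moving-average window in samples.
#' @return Emphasized envelope, same length.
#' @export
emphasize <- function(env, gain = 20, window = 1000L) {
  movingAverage(gain * as.numeric(env)^2, window)
}

#' Detect envelope peaks with a minimum-distance constraint
#'
#' Finds strict interior local maxima of the envelope (for flat-topped
#' maxima, the first sample of the plateau) and greedily keeps them in
#' decreasing height order, rejecting any candidate closer than
#' `minDistance` samples to an already-accepted peak; among equal heights
#' the lower index wins. The caller derives `minDistance` from the main
#' frequency: half the period, `round(fs / mainFreq / 2)`.
#'
#' @param env numeric vector.
#' @param minDistance minimum separation between kept peaks, in samples.
#' @return Sorted integer vector of peak indices (possibly empty).
#' @export
detectPeaks <- function(env, minDistance = 1L) {
  env <- as.numeric(env)
  minDistance <- max(1L, as.integer(minDistance))
  n <- length(env)
  if (n < 3L) return(integer(0))
  # compress equal-value runs, then test runs against distinct neighbours
  r <- rle(env)
  v <- r$values
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(v)
  if (k < 3L) return(integer(0))
  isMax <- c(FALSE, v[2:(k - 1)] > v[1:(k - 2)] &
                    v[2:(k - 1)] > v[3:k], FALSE)
  cand <- starts[isMax]
  if (length(cand) == 0L) return(integer(0))
  ord <- order(-env[cand], cand)
  kept <- integer(0)
  for (p in cand[ord]) {
    if (length(kept) == 0L || all(abs(kept - p) >= minDistance))
      kept <- c(kept, p)
  }
  sort(kept)
}

#' Segment boundaries from envelope peaks
#'
#' For each peak of height `h`, walks left and right to the nearest
#' samples where the envelope drops below `(1 - boundaryFraction) * h`;
#' the enclosed interval — the part of the peak spanning the top
#' `boundaryFraction` of its amplitude range — is the episode. Peaks whose
#' extents overlap or touch are merged; extents are clipped to the signal
#' bounds when no down-crossing exists.
#'
#' @param env numeric vector.
#' @param peaks integer vector of peak indices into `env`.
#' @param boundaryFraction fraction of the peak amplitude enclosed
#'   (default 0.8).
#' @return An [IRanges::IRanges] of merged episode intervals.
#' @export
segmentsFromPeaks <- function(env, peaks, boundaryFraction = 0.8) {
  env <- as.numeric(env)
  n <- length(env)
  peaks <- as.integer(peaks)
  if (any(peaks < 1L | peaks > n)) stop("peak index out of range")
  if (length(peaks) == 0L)
    return(IRanges::IRanges())
  lo <- integer(length(peaks))
  hi <- integer(length(peaks))
  for (j in seq_along(peaks)) {
    p <- peaks[j]
    thr <- (1 - boundaryFraction) * env[p]
    l <- p
    while (l > 1L && env[l - 1L] >= thr) l <- l - 1L
    r <- p
    while (r < n && env[r + 1L] >= thr) r <- r + 1L
    lo[j] <- l
    hi[j] <- r
  }
  IRanges::reduce(IRanges::IRanges(start = lo, end = hi))
}

#' Segment a TMJ recording with the DSP pipeline
#'
#' Runs the full deterministic chain: [rectifyNormalize()] →
#' [lowpassElliptic()] at the [mainFrequency()] cutoff → [movingAverage()]
#' → [emphasize()] → [detectPeaks()] (minimum distance of half the main
#' period) → [segmentsFromPeaks()] → [segmentsToMask()]. The result is a
#' per-sample 0/1 mask of the input length. The pipeline is deterministic
#' and invariant to amplitude scaling of the input.
#'
#' @param record an [AudioRecord-class].
#' @param config a [dspConfig()].
#' @return Integer 0/1 mask of length `nSamples(record)`.
#' @examples
#' ann <- generateRecord(syntheticConfig(nRepetitions = 6), seed = 7)
#' m <- dspSegment(audioRecord(ann))
#' length(maskToSegments(m))
#' @export
dspSegment <- function(record, config = dspConfig()) {
  stopifnot(is(record, "AudioRecord"))
  if (!inherits(config, "tmjDspConfig"))
    stop("config must come from dspConfig()")
  fs <- record@fs
  env <- rectifyNormalize(record)
  f0 <- mainFrequency(record, fminHz = config$fminHz)
  env <- lowpassElliptic(env, f0, fs, order = config$filterOrder,
                         rippleDb = config$passbandRippleDb,
                         attenDb = config$stopbandAttenDb)
  env <- movingAverage(env, config$maWindowSamples)
  env <- emphasize(env, config$gain, config$maWindow2Samples)
  minDist <- max(1L, as.integer(round(fs / f0 / 2)))
  peaks <- detectPeaks(env, minDist)
  segs <- segmentsFromPeaks(env, peaks, config$boundaryFraction)
  segmentsToMask(segs, nSamples(record))
}
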