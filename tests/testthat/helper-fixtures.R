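# Shared helpers for the test suite. Fixtures are generated in code; the
# fast config keeps unit-test records short (~8 s) while the full-length
# defaults are reserved for the corpus-level acceptance checks.

fastConfig <- function(...) {
  syntheticConfig(cyclePeriodS = 1.2, burstDurationS = 0.4,
                  leadInS = 0.5, leadOutS = 0.5, ...)
}

fastRecord <- function(seed = 1, ...) {
  generateRecord(fastConfig(...), seed = seed)
}

tinyModelConfig <- function(...) {
  modelConfig(inputLen = 32L, channels = c(2L, 3L), kernelSize = 3L,
              poolWindow = 2L, lstmLayers = 2L, lstmHidden = 4L, ...)
}

# flatten a nested parameter list to one numeric vector, and rebuild
flattenParams <- function(x) {
  if (is.list(x)) unlist(lapply(x, flattenParams)) else as.numeric(x)
}

rebuildParams <- function(template, v, pos = 1) {
  if (is.list(template)) {
    out <- template
    for (i in seq_along(template)) {
      r <- rebuildParams(template[[i]], v, pos)
      out[[i]] <- r$x
      pos <- r$pos
    }
    return(list(x = out, pos = pos))
  }
  n <- length(template)
  x <- template
  x[] <- v[pos:(pos + n - 1)]
  list(x = x, pos = pos + n)
}

# independent oracle: O(n*w) windowed mean with clipped (shrinking) edges
bruteMovingAverage <- function(x, w) {
  n <- length(x)
  left <- w %/% 2
  right <- w - 1 - left
  sapply(seq_len(n), function(i) {
    lo <- max(1, i - left)
    hi <- min(n, i + right)
    mean(x[lo:hi])
  })
}

# independent oracle: per-window minimum of absolute values
bruteMinAbsPool <- function(x, w) {
  n <- length(x)
  starts <- seq(1, n, by = w)
  sapply(starts, function(s) min(abs(x[s:min(s + w - 1, n)])))
}

# independent oracle: strict-interior local maxima (plateau start), then
# greedy by height with a minimum-distance constraint
brutePeaks <- function(env, minDist) {
  n <- length(env)
  cand <- integer(0)
  for (i in seq_len(n)) {
    # previous distinct value
    l <- i - 1
    while (l >= 1 && env[l] == env[i]) l <- l - 1
    if (l >= 1 && i >= 2 && env[i - 1] == env[i]) next  # not plateau start
    r <- i + 1
    while (r <= n && env[r] == env[i]) r <- r + 1
    if (l >= 1 && r <= n && env[l] < env[i] && env[r] < env[i])
      cand <- c(cand, i)
  }
  ord <- cand[order(-env[cand], cand)]
  kept <- integer(0)
  for (p in ord)
    if (!length(kept) || all(abs(kept - p) >= minDist)) kept <- c(kept, p)
  sort(kept)
}
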