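# Fixture builders and independent oracles used across the suite.

# Epochs container around a plain channels x samples matrix (one trial).
matrixEpochs <- function(mat, fs, labels = NULL,
                         channelType = "visual", musicType = "nostalgic") {
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(mat)))
  arr <- array(0, dim = c(1, nrow(mat), ncol(mat)))
  arr[1, , ] <- mat
  new("EEGEpochs", data = arr, fs = fs, channelLabels = labels,
      eogLabels = character(0),
      conditions = data.frame(channelType = channelType,
                              musicType = musicType,
                              stringsAsFactors = FALSE),
      window = c(0, ncol(mat) / fs),
      baselineWindow = c(NA_real_, NA_real_),
      rejected = FALSE, provenance = list())
}

# Recording container around a matrix, with optional events/EOG.
matrixRecording <- function(mat, fs, labels = NULL, eog = character(0),
                            events = NULL) {
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(mat)))
  rownames(mat) <- labels
  if (is.null(events))
    events <- data.frame(onset = integer(0), channelType = character(0),
                         musicType = character(0), stringsAsFactors = FALSE)
  new("EEGRecording", data = mat, fs = fs, channelLabels = labels,
      eogLabels = eog, reference = "other", events = events,
      provenance = list())
}

# Small, artifact-free simulation configuration for fast tests.
tinyCfg <- function(nSubjects = 2, nChannels = 8, fs = 128, trialSec = 4,
                    nTrialsPerCell = 1, seed = 1,
                    bandCoupling = defaultBandCoupling(),
                    blinkRate = 0, lineNoiseUv = 0, spikeProb = 0, ...) {
  simConfig(nSubjects = nSubjects, nChannels = nChannels, fs = fs,
            trialSec = trialSec, baselineSec = 1, gapSec = 0.5,
            nTrialsPerCell = nTrialsPerCell, bandCoupling = bandCoupling,
            blinkRate = blinkRate, lineNoiseUv = lineNoiseUv,
            spikeProb = spikeProb, seed = seed, ...)
}

# Random symmetric weight matrix with zero diagonal; `sparsity` = fraction of
# absent edges.
randomWeightMatrix <- function(n, sparsity = 0.3) {
  W <- matrix(0, n, n)
  up <- which(upper.tri(W))
  w <- runif(length(up))
  w[runif(length(up)) < sparsity] <- 0
  W[up] <- w
  W + t(W)
}

# --- brute-force graph oracles (independent of the implementation) --------

# All-pairs shortest paths by exhaustive simple-path enumeration over
# lengths 1/w. Only feasible for small n.
bruteDistances <- function(W) {
  n <- nrow(W)
  L <- ifelse(W > 0, 1 / W, Inf)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  enumerate <- function(current, target, visited, acc) {
    if (current == target) return(acc)
    best <- Inf
    for (nxt in seq_len(n)) {
      if (visited[nxt] || !is.finite(L[current, nxt])) next
      v <- visited; v[nxt] <- TRUE
      best <- min(best, enumerate(nxt, target, v, acc + L[current, nxt]))
    }
    best
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    visited <- rep(FALSE, n); visited[i] <- TRUE
    d[i, j] <- enumerate(i, j, visited, 0)
  }
  d
}

bruteStrength <- function(W) {
  n <- nrow(W)
  vapply(seq_len(n), function(i) sum(W[i, -i]), 0)
}

bruteOnnela <- function(W) {
  n <- nrow(W)
  wh <- if (max(W) > 0) W / max(W) else W
  out <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(W[i, ] > 0)
    if (k < 2) next
    acc <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j == i || h == i || j == h) next
      acc <- acc + (wh[i, j] * wh[i, h] * wh[j, h])^(1 / 3)
    }
    out[i] <- acc / (k * (k - 1))
  }
  out
}

bruteGlobalEff <- function(d) {
  off <- d[row(d) != col(d)]
  mean(ifelse(is.finite(off) & off > 0, 1 / off, 0))
}

bruteCharPath <- function(d) {
  off <- d[row(d) != col(d)]
  mean(off[is.finite(off)])
}

bruteLocalEff <- function(W) {
  n <- nrow(W)
  eff <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(W[i, ] > 0)
    if (length(nb) < 2) next
    eff[i] <- bruteGlobalEff(bruteDistances(W[nb, nb, drop = FALSE]))
  }
  mean(eff)
}
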