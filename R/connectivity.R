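# Weighted phase lag index (WPLI) connectivity. The estimator follows the
# magnitude-weighted definition: per channel pair and frequency bin,
# WPLI = |E[Im S_xy]| / E[|Im S_xy|], with the expectation taken over
# Hann-windowed segments pooled across all retained epochs of a condition.
# Zero-lag coupling has Im S = 0 and contributes nothing, which is what
# makes the index robust to volume conduction.

#' Per-segment cross-spectral samples in one band
#'
#' Computes the Hann-windowed segment Fourier coefficients of the requested
#' channels at every FFT bin inside the band (half-open [lo, hi) bin
#' membership), pooling segments across the retained epochs of the selected
#' condition. Segmentation parameters default to the Welch settings of the
#' spectral module so PSD and connectivity share one spectral estimate.
#'
#' @param ep an \code{\linkS4class{EEGEpochs}}.
#' @param band band name (in \code{bands}) or a one-row band data.frame.
#' @param segSec,overlap Welch segmentation (default 2 s Hann, 50\%).
#' @param musicType,channelType optional condition filters.
#' @param channels channels to include (default: scalp channels).
#' @param bands band table used to resolve \code{band} by name.
#' @return a \code{\linkS4class{CrossSpectralSamples}}.
#' @export
crossSpectra <- function(ep, band, segSec = 2, overlap = 0.5,
                         musicType = NULL, channelType = NULL,
                         channels = NULL, bands = canonicalBands()) {
  b <- bandRow(band, bands)
  sf <- epochSegmentFFT(ep, segSec, overlap, musicType, channelType, channels)
  sel <- which(sf$freqs >= b$lo - 1e-9 & sf$freqs < b$hi - 1e-9)
  if (!length(sel)) stop(sprintf("no frequency bins inside band %s (%g-%g Hz)",
                                 b$name, b$lo, b$hi))
  if (sf$nSegments < 2L) stop("fewer than 2 segments: WPLI undefined")
  new("CrossSpectralSamples",
      coef = sf$coef[, sel, , drop = FALSE],
      freqs = sf$freqs[sel], band = b,
      channelLabels = sf$channels, nSegments = as.integer(sf$nSegments))
}

#' Cross-spectral samples of one channel pair
#'
#' @param cs a \code{\linkS4class{CrossSpectralSamples}}.
#' @param i,j channel labels or indices.
#' @return complex matrix bins x segments of S_ij = X_i * Conj(X_j).
#' @export
pairSamples <- function(cs, i, j) {
  if (is.character(i)) i <- match(i, cs@channelLabels)
  if (is.character(j)) j <- match(j, cs@channelLabels)
  xi <- cs@coef[i, , , drop = FALSE]
  xj <- cs@coef[j, , , drop = FALSE]
  matrix(xi * Conj(xj), nrow = length(cs@freqs))
}

#' The WPLI estimator on raw imaginary cross-spectral samples
#'
#' \code{|sum(imS)| / sum(|imS|)}, with the 0/0 case defined as 0 (the
#' convention for degenerate zero-lag pairs).
#'
#' @param imS numeric vector of Im(S_xy) samples across segments.
#' @return WPLI value in [0, 1].
#' @export
#' @examples
#' wpliEstimate(c(1, 2, -1))  # 0.5
wpliEstimate <- function(imS) {
  den <- sum(abs(imS))
  if (den == 0) return(0)
  abs(sum(imS)) / den
}

#' WPLI connectivity matrix
#'
#' Assembles the symmetric channel x channel WPLI matrix from cross-spectral
#' samples: per pair and frequency bin, \code{|mean Im S| / mean |Im S|}
#' over segments; the band value is the unweighted mean across the band's
#' bins (a power-weighted mean is available via \code{binWeights}). Pairs
#' whose denominator is zero at some bin (perfect zero-lag) take the value 0
#' at that bin; their count is recorded in \code{meta$nDegenerate}.
#'
#' @param cs a \code{\linkS4class{CrossSpectralSamples}}.
#' @param condition named character condition labels carried to the output.
#' @param subject subject identifier.
#' @param binWeights \code{"uniform"} (default) or \code{"power"} (weight
#'   bins by mean cross-power magnitude).
#' @return a \code{\linkS4class{ConnectivityMatrix}}.
#' @export
wpli <- function(cs, condition = character(), subject = "",
                 binWeights = c("uniform", "power")) {
  binWeights <- match.arg(binWeights)
  nCh <- length(cs@channelLabels)
  nF <- length(cs@freqs)
  nS <- cs@nSegments
  num <- array(0, dim = c(nCh, nCh, nF))
  den <- array(0, dim = c(nCh, nCh, nF))
  for (f in seq_len(nF)) {
    M <- matrix(cs@coef[, f, ], nrow = nCh)
    A <- Re(M); B <- Im(M)
    for (s in seq_len(nS)) {
      imS <- B[, s] %o% A[, s] - A[, s] %o% B[, s]   # Im(X_i Conj(X_j))
      num[, , f] <- num[, , f] + imS
      den[, , f] <- den[, , f] + abs(imS)
    }
  }
  perBin <- abs(num) / ifelse(den > 0, den, 1)
  perBin[den == 0] <- 0
  if (binWeights == "uniform") {
    W <- apply(perBin, c(1, 2), mean)
  } else {
    pows <- vapply(seq_len(nF), function(f)
      mean(abs(matrix(cs@coef[, f, ], nrow = nCh))^2), 0)
    W <- apply(sweep(perBin, 3, pows, `*`), c(1, 2), sum) / sum(pows)
  }
  diag(W) <- 0
  W <- (W + t(W)) / 2
  dimnames(W) <- list(cs@channelLabels, cs@channelLabels)
  new("ConnectivityMatrix", W = W, band = cs@band,
      condition = condition, subject = subject,
      meta = list(nSegments = nS,
                  nDegenerate = sum(apply(den == 0, c(1, 2), any)[upper.tri(W)]),
                  binWeights = binWeights))
}

#' Full per-band WPLI from epochs
#'
#' Convenience wrapper: \code{\link{crossSpectra}} then \code{\link{wpli}}.
#'
#' @inheritParams crossSpectra
#' @inheritParams wpli
#' @return a \code{\linkS4class{ConnectivityMatrix}}.
#' @export
wpliMatrix <- function(ep, band, segSec = 2, overlap = 0.5,
                       musicType = NULL, channelType = NULL,
                       channels = NULL, bands = canonicalBands(),
                       subject = "") {
  cs <- crossSpectra(ep, band, segSec, overlap, musicType, channelType,
                     channels, bands)
  cond <- c(musicType = if (is.null(musicType)) "all" else paste(musicType, collapse = "+"))
  wpli(cs, condition = cond, subject = subject)
}

#' Group-average connectivity matrix
#'
#' Element-wise mean of per-subject WPLI matrices sharing one montage and
#' band; the number of subjects averaged is recorded in \code{meta$n}.
#'
#' @param matrices list of \code{\linkS4class{ConnectivityMatrix}} objects.
#' @return a \code{\linkS4class{ConnectivityMatrix}} group mean.
#' @export
groupConnectivity <- function(matrices) {
  stopifnot(length(matrices) >= 1L)
  ref <- matrices[[1]]
  for (m in matrices[-1]) {
    if (!identical(rownames(m@W), rownames(ref@W)))
      stop("montage mismatch across subjects")
    if (!identical(m@band$name, ref@band$name))
      stop("band mismatch across subjects")
  }
  W <- Reduce(`+`, lapply(matrices, function(m) m@W)) / length(matrices)
  new("ConnectivityMatrix", W = W, band = ref@band,
      condition = ref@condition, subject = "",
      meta = list(n = length(matrices)))
}

#' Mean off-diagonal connectivity
#'
#' Mean of the upper-triangular (off-diagonal) entries — the "mean WPLI"
#' summary used in whole-matrix comparisons.
#'
#' @param x a \code{\linkS4class{ConnectivityMatrix}} or square matrix.
#' @return scalar mean.
#' @export
meanConnectivity <- function(x) {
  W <- if (is(x, "ConnectivityMatrix")) x@W else x
  mean(W[upper.tri(W)])
}
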