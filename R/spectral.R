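# Welch power spectral density and band aggregation. A single Hann-windowed
# overlapping-segment FFT engine backs both the PSD estimates and the
# cross-spectral samples used by the WPLI estimator, so spectra and
# connectivity share one spectral decomposition.

# Segment one channels x samples matrix into Hann-windowed, mean-detrended,
# overlapping segments and FFT each. Returns the one-sided coefficients
# (channels x bins x segments), the frequency grid, and the density
# normalization 2 / (fs * sum(w^2)) such that psd = |X|^2 * norm (with DC
# and Nyquist bins not doubled).
segmentFFT <- function(mat, fs, segSec, overlap) {
  nSamp <- ncol(mat)
  segLen <- round(segSec * fs)
  if (segLen < 64) stop("segment too short: need seg_sec * fs >= 64 samples")
  if (segLen > nSamp) stop("segment longer than the data")
  step <- max(1L, round(segLen * (1 - overlap)))
  starts <- seq(1L, nSamp - segLen + 1L, by = step)
  w <- hannWindow(segLen)
  nf <- segLen %/% 2 + 1L
  coef <- array(0i, dim = c(nrow(mat), nf, length(starts)))
  for (s in seq_along(starts)) {
    seg <- mat[, starts[s] + seq_len(segLen) - 1L, drop = FALSE]
    seg <- seg - rowMeans(seg)
    segW <- sweep(seg, 2, w, `*`)
    coef[, , s] <- t(apply(segW, 1, fft))[, seq_len(nf), drop = FALSE]
  }
  freqs <- seq(0, fs / 2, length.out = nf)
  list(coef = coef, freqs = freqs, norm = 2 / (fs * sum(w^2)),
       segLen = segLen, nSegments = length(starts))
}

# Pool segment FFTs over the retained trials of an EpochSet.
epochSegmentFFT <- function(ep, segSec, overlap, musicType = NULL,
                            channelType = NULL, channels = NULL) {
  trials <- retainedTrials(ep, musicType, channelType)
  if (is.null(channels)) channels <- scalpLabels(ep)
  chIdx <- match(channels, ep@channelLabels)
  if (anyNA(chIdx)) stop("unknown channels requested")
  pieces <- lapply(trials, function(t)
    segmentFFT(matrix(ep@data[t, chIdx, ], nrow = length(chIdx)),
               ep@fs, segSec, overlap))
  coef <- array(0i, dim = c(length(chIdx), dim(pieces[[1]]$coef)[2],
                            sum(vapply(pieces, function(p) p$nSegments, 0L))))
  at <- 0L
  for (p in pieces) {
    coef[, , at + seq_len(p$nSegments)] <- p$coef
    at <- at + p$nSegments
  }
  list(coef = coef, freqs = pieces[[1]]$freqs, norm = pieces[[1]]$norm,
       nSegments = at, channels = channels)
}

#' Welch power spectral density of an epoch set
#'
#' Hann-windowed, overlapping-segment averaged periodogram per channel
#' (one-sided density normalization, uV^2/Hz), averaged over all segments of
#' the retained (non-rejected) epochs of the selected condition.
#'
#' @param ep an \code{\linkS4class{EEGEpochs}}.
#' @param segSec segment length in seconds (default 2).
#' @param overlap segment overlap fraction (default 0.5).
#' @param musicType,channelType optional condition filters.
#' @param channels channels to include (default: all scalp channels).
#' @return a \code{\linkS4class{SpectralSummary}} (PSD only; see
#'   \code{\link{bandAggregate}} for band power).
#' @export
welchPSD <- function(ep, segSec = 2, overlap = 0.5, musicType = NULL,
                     channelType = NULL, channels = NULL) {
  sf <- epochSegmentFFT(ep, segSec, overlap, musicType, channelType, channels)
  nf <- length(sf$freqs)
  psd <- apply(abs(sf$coef)^2, c(1, 2), mean) * sf$norm
  psd[, 1] <- psd[, 1] / 2                      # DC not doubled
  psd[, nf] <- psd[, nf] / 2                    # Nyquist not doubled
  new("SpectralSummary", freqs = sf$freqs, psd = psd,
      bandPower = matrix(numeric(0), nrow = nrow(psd), ncol = 0),
      relativePower = matrix(numeric(0), nrow = nrow(psd), ncol = 0),
      regionMeans = data.frame(), bands = data.frame(),
      channelLabels = sf$channels,
      meta = list(segSec = segSec, overlap = overlap,
                  nSegments = sf$nSegments,
                  musicType = musicType, channelType = channelType))
}

#' Aggregate a PSD into band powers
#'
#' Band power is the trapezoid integral of the PSD over each band's span on
#' the FFT grid. Integration uses closed intervals so that the five bands
#' tile the 1-50 Hz axis exactly (a shared band edge contributes its two
#' half-bins to the two adjacent bands); frequency-bin \emph{membership}
#' queries use the half-open convention [lo, hi) — see \code{\link{bandOf}}.
#' Relative power divides each band by the sum over the defined bands; when
#' the total is zero the relative powers are set to \code{NA} and flagged in
#' \code{meta$relativeUndefined} rather than propagating NaN. Region means
#' average band power over the montage's electrode regions.
#'
#' @param s a \code{\linkS4class{SpectralSummary}} from \code{\link{welchPSD}}.
#' @param bands band table (default \code{\link{canonicalBands}}).
#' @return the summary with \code{bandPower}, \code{relativePower} and
#'   \code{regionMeans} filled in.
#' @export
bandAggregate <- function(s, bands = canonicalBands()) {
  f <- s@freqs
  if (min(bands$lo) < min(f) - 1e-9 || max(bands$hi) > max(f) + 1e-9)
    stop("band edges outside the PSD frequency grid")
  nb <- nrow(bands)
  bp <- matrix(0, nrow = nrow(s@psd), ncol = nb,
               dimnames = list(s@channelLabels, bands$name))
  for (b in seq_len(nb)) {
    sel <- which(f >= bands$lo[b] - 1e-9 & f <= bands$hi[b] + 1e-9)
    if (length(sel) < 2L) stop(sprintf("band '%s' spans < 2 frequency bins", bands$name[b]))
    for (ch in seq_len(nrow(s@psd)))
      bp[ch, b] <- trapezoid(f[sel], s@psd[ch, sel])
  }
  tot <- rowSums(bp)
  rel <- bp / tot
  undef <- tot <= 0
  rel[undef, ] <- NA_real_
  out <- s
  out@bandPower <- bp
  out@relativePower <- rel
  out@bands <- bands
  out@meta$relativeUndefined <- as.integer(which(undef))
  regions <- electrodeRegions(s@channelLabels)
  if (length(regions)) {
    rm <- do.call(rbind, lapply(names(regions), function(r) {
      sel <- match(regions[[r]], s@channelLabels)
      data.frame(region = r, band = bands$name,
                 power = colMeans(bp[sel, , drop = FALSE]),
                 stringsAsFactors = FALSE)
    }))
    rownames(rm) <- NULL
    out@regionMeans <- rm
  }
  validObject(out)
  out
}

#' Tidy band-power table
#'
#' Long-format export of an aggregated spectral summary: one row per
#' electrode x band with absolute and relative power.
#'
#' @param s an aggregated \code{\linkS4class{SpectralSummary}}.
#' @return data.frame with columns \code{electrode}, \code{band},
#'   \code{power}, \code{rel_power}.
#' @export
bandPowerTable <- function(s) {
  if (!ncol(s@bandPower)) stop("run bandAggregate() first")
  data.frame(
    electrode = rep(s@channelLabels, times = ncol(s@bandPower)),
    band = rep(colnames(s@bandPower), each = nrow(s@bandPower)),
    power = as.numeric(s@bandPower),
    rel_power = as.numeric(s@relativePower),
    stringsAsFactors = FALSE
  )
}
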