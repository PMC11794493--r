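# Preprocessing chain: zero-phase filters -> bad-channel interpolation ->
# epoching with baseline correction -> ICA ocular removal -> linked-mastoid
# re-reference -> amplitude rejection. Every operation returns a new object
# and appends a provenance entry; inputs are never mutated.

applyFiltfilt <- function(data, filt) {
  out <- data
  for (i in seq_len(nrow(data))) out[i, ] <- signal::filtfilt(filt, data[i, ])
  out
}

#' Zero-phase band-pass filter
#'
#' Butterworth band-pass applied forward-backward (zero phase). The high-pass
#' and low-pass halves are applied as separate 4th-order sections for
#' numerical stability at very low cutoffs (the default analysis band is
#' 0.1-50 Hz, where a single band-pass design is badly conditioned).
#'
#' @param rec an \code{\linkS4class{EEGRecording}}.
#' @param lo,hi band edges in Hz; \code{0 < lo < hi < fs/2}.
#' @param order Butterworth order per section (default 4).
#' @return a filtered \code{EEGRecording}.
#' @export
bandpassFilter <- function(rec, lo = 0.1, hi = 50, order = 4) {
  fs <- rec@fs
  if (!(lo > 0 && lo < hi)) stop("need 0 < lo < hi")
  if (hi >= fs / 2) stop(sprintf("hi=%g Hz is at or above Nyquist (%g Hz)", hi, fs / 2))
  hp <- signal::butter(order, lo / (fs / 2), type = "high")
  lp <- signal::butter(order, hi / (fs / 2), type = "low")
  out <- rec
  # remove DC explicitly: a high-pass this low cannot cancel a constant
  # offset within a finite record
  demeaned <- rec@data - rowMeans(rec@data)
  out@data <- applyFiltfilt(applyFiltfilt(demeaned, hp), lp)
  validObject(out)
  addProvenance(out, "bandpass", list(lo = lo, hi = hi, order = order))
}

#' Zero-phase notch filter
#'
#' Butterworth band-stop applied forward-backward, for line-noise removal
#' (default 49-51 Hz).
#'
#' @inheritParams bandpassFilter
#' @param lo,hi stop-band edges in Hz.
#' @export
notchFilter <- function(rec, lo = 49, hi = 51, order = 4) {
  fs <- rec@fs
  if (!(lo > 0 && lo < hi)) stop("need 0 < lo < hi")
  if (hi >= fs / 2) stop(sprintf("hi=%g Hz is at or above Nyquist (%g Hz)", hi, fs / 2))
  bs <- signal::butter(order, c(lo, hi) / (fs / 2), type = "stop")
  out <- rec
  out@data <- applyFiltfilt(rec@data, bs)
  validObject(out)
  addProvenance(out, "notch", list(lo = lo, hi = hi, order = order))
}

#' Interpolate bad channels
#'
#' Replaces each bad channel by an inverse-distance-weighted (squared
#' great-circle distance on the montage sphere) combination of the good
#' scalp channels. Good channels are untouched; EOG channels are never used
#' as donors.
#'
#' @param rec an \code{\linkS4class{EEGRecording}}.
#' @param bad character vector of bad channel labels (may be empty).
#' @return an \code{EEGRecording} with bad channels replaced.
#' @export
interpolateBad <- function(rec, bad) {
  if (length(bad) == 0L) return(addProvenance(rec, "interpolate", list(bad = character(0))))
  if (!all(bad %in% rec@channelLabels))
    stop("unknown bad channels: ", paste(setdiff(bad, rec@channelLabels), collapse = ", "))
  good <- setdiff(setdiff(rec@channelLabels, rec@eogLabels), bad)
  if (length(good) < 4L) stop("need at least 4 good scalp channels to interpolate")
  mon <- standardMontage()
  pos <- as.matrix(mon[match(rec@channelLabels, mon$label), c("x", "y", "z")])
  rownames(pos) <- rec@channelLabels
  if (anyNA(pos[bad, ])) stop("no montage position for: ",
                              paste(bad[apply(is.na(pos[bad, , drop = FALSE]), 1, any)], collapse = ", "))
  out <- rec
  for (b in bad) {
    cosang <- pos[good, , drop = FALSE] %*% pos[b, ]
    d <- acos(pmin(1, pmax(-1, cosang)))
    w <- 1 / pmax(d, 1e-6)^2
    w <- w / sum(w)
    out@data[b, ] <- as.numeric(t(w) %*% rec@data[good, , drop = FALSE])
  }
  validObject(out)
  addProvenance(out, "interpolate", list(bad = bad))
}

resolveMastoids <- function(labels, mastoids) {
  syn <- c(M1 = "TP9", M2 = "TP10")
  resolved <- vapply(mastoids, function(m) {
    cands <- unique(c(m, unname(syn[m]), names(syn)[syn == m]))
    hit <- intersect(cands[!is.na(cands)], labels)
    if (length(hit)) hit[1] else NA_character_
  }, character(1))
  if (anyNA(resolved))
    stop("mastoid channel(s) not found: ",
         paste(mastoids[is.na(resolved)], collapse = ", "),
         "; available: ", paste(labels, collapse = ", "))
  unname(resolved)
}

#' Re-reference to linked mastoids
#'
#' Subtracts the mean of the two mastoid channels from every non-EOG channel
#' and tags the data as linked-mastoid referenced. \code{M1}/\code{M2} are
#' accepted as synonyms for \code{TP9}/\code{TP10}. Works on a continuous
#' recording or on an epoch set (per trial), since the prescribed chain
#' re-references after epoching and ICA.
#'
#' @param x an \code{\linkS4class{EEGRecording}} or
#'   \code{\linkS4class{EEGEpochs}}.
#' @param mastoids pair of mastoid labels (default \code{c("TP9", "TP10")}).
#' @return the re-referenced object.
#' @export
setGeneric("rereferenceLinkedMastoids",
           function(x, mastoids = c("TP9", "TP10"))
             standardGeneric("rereferenceLinkedMastoids"))

#' @rdname rereferenceLinkedMastoids
#' @export
setMethod("rereferenceLinkedMastoids", "EEGRecording",
  function(x, mastoids = c("TP9", "TP10")) {
    resolved <- resolveMastoids(x@channelLabels, mastoids)
    ref <- colMeans(x@data[resolved, , drop = FALSE])
    out <- x
    scalp <- setdiff(x@channelLabels, x@eogLabels)
    out@data[scalp, ] <- sweep(x@data[scalp, , drop = FALSE], 2, ref)
    out@reference <- "linked-mastoid"
    validObject(out)
    addProvenance(out, "rereference", list(mastoids = resolved))
  })

#' @rdname rereferenceLinkedMastoids
#' @export
setMethod("rereferenceLinkedMastoids", "EEGEpochs",
  function(x, mastoids = c("TP9", "TP10")) {
    resolved <- resolveMastoids(x@channelLabels, mastoids)
    mi <- match(resolved, x@channelLabels)
    scalp <- which(!(x@channelLabels %in% x@eogLabels))
    out <- x
    for (t in seq_len(dim(x@data)[1])) {
      ref <- colMeans(matrix(x@data[t, mi, ], nrow = length(mi)))
      out@data[t, scalp, ] <- x@data[t, scalp, ] -
        matrix(ref, nrow = length(scalp), ncol = length(ref), byrow = TRUE)
    }
    out@provenance <- c(out@provenance,
                        list(list(op = "rereference",
                                  params = list(mastoids = resolved))))
    out
  })

#' Cut stimulus-locked epochs and baseline-correct
#'
#' Segments the recording into \code{[onset + t0, onset + t1)} windows and
#' subtracts, per epoch and channel, the mean over the baseline window
#' (default: the 5 s fixation interval preceding stimulus onset). Trials
#' whose window falls outside the recording are dropped with a warning, not
#' a global failure.
#'
#' @param rec an \code{\linkS4class{EEGRecording}} with events.
#' @param events optional events data.frame overriding \code{rec}'s events.
#' @param t0,t1 epoch window in seconds relative to onset (default 0, 30).
#' @param baseline length-2 numeric, baseline window in seconds relative to
#'   onset (default \code{c(-5, 0)}); \code{NULL} skips baseline correction.
#' @return an \code{\linkS4class{EEGEpochs}}.
#' @export
epochAndBaseline <- function(rec, events = NULL, t0 = 0, t1 = 30,
                             baseline = c(-5, 0)) {
  if (is.null(events)) events <- rec@events
  if (!nrow(events)) stop("no events to epoch around")
  fs <- rec@fs
  n <- ncol(rec@data)
  len <- round((t1 - t0) * fs)
  keep <- logical(nrow(events))
  for (i in seq_len(nrow(events))) {
    a <- events$onset[i] + round(t0 * fs)
    bLo <- if (is.null(baseline)) a else events$onset[i] + round(baseline[1] * fs)
    keep[i] <- min(a, bLo) >= 0 && (a + len) <= n
    if (!keep[i])
      warning(sprintf("trial %d dropped: window outside recording", i))
  }
  events <- events[keep, , drop = FALSE]
  if (!nrow(events)) stop("all trials fell outside the recording")
  arr <- array(0, dim = c(nrow(events), nrow(rec@data), len))
  for (i in seq_len(nrow(events))) {
    a <- events$onset[i] + round(t0 * fs)
    ep <- rec@data[, a + seq_len(len), drop = FALSE]
    if (!is.null(baseline)) {
      b0 <- events$onset[i] + round(baseline[1] * fs)
      b1 <- events$onset[i] + round(baseline[2] * fs)
      bmean <- rowMeans(rec@data[, (b0 + 1):b1, drop = FALSE])
      ep <- ep - bmean
    }
    arr[i, , ] <- ep
  }
  new("EEGEpochs", data = arr, fs = fs, channelLabels = rec@channelLabels,
      eogLabels = rec@eogLabels,
      conditions = events[, c("channelType", "musicType"), drop = FALSE],
      window = c(t0, t1),
      baselineWindow = if (is.null(baseline)) c(NA_real_, NA_real_) else baseline,
      rejected = logical(nrow(events)),
      provenance = c(rec@provenance,
                     list(list(op = "epoch",
                               params = list(t0 = t0, t1 = t1,
                                             baseline = baseline)))))
}

#' Reject epochs by peak amplitude
#'
#' Marks as rejected every trial in which any scalp channel exceeds the
#' threshold in absolute amplitude at any sample ("exceeding" is read as a
#' strict inequality, evaluated after baseline correction). EOG channels are
#' ignored. Rejected trials stay in the container but are excluded from all
#' downstream averages.
#'
#' @param ep an \code{\linkS4class{EEGEpochs}}.
#' @param threshold rejection threshold in uV (default 75; \code{Inf}
#'   disables).
#' @return the \code{EEGEpochs} with an updated rejection mask.
#' @export
rejectAmplitude <- function(ep, threshold = 75) {
  stopifnot(threshold > 0)
  scalpIdx <- which(!(ep@channelLabels %in% ep@eogLabels))
  rej <- ep@rejected
  for (i in seq_len(dim(ep@data)[1])) {
    peak <- max(abs(ep@data[i, scalpIdx, ]))
    if (peak > threshold) rej[i] <- TRUE
  }
  out <- ep
  out@rejected <- rej
  out@provenance <- c(out@provenance,
                      list(list(op = "rejectAmplitude",
                                params = list(threshold = threshold,
                                              nRejected = sum(rej)))))
  out
}

#' Retained (non-rejected) trial indices, optionally by condition
#'
#' @param ep an \code{\linkS4class{EEGEpochs}}.
#' @param musicType,channelType optional condition filters.
#' @return integer trial indices.
#' @export
retainedTrials <- function(ep, musicType = NULL, channelType = NULL) {
  sel <- !ep@rejected
  if (!is.null(musicType)) sel <- sel & ep@conditions$musicType %in% musicType
  if (!is.null(channelType)) sel <- sel & ep@conditions$channelType %in% channelType
  idx <- which(sel)
  if (!length(idx)) stop("no retained trials for the requested condition")
  idx
}
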