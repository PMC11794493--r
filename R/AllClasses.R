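#' @import methods
#' @importFrom stats fft rnorm runif rpois rbinom var sd cor aov t.test pf pt
#'   p.adjust setNames complete.cases
#' @importFrom utils write.csv read.csv head packageVersion
NULL

#' Continuous multichannel EEG recording
#'
#' Container for a continuous EEG recording: a channels x samples matrix in
#' microvolts, its sampling rate, channel labels (extended 10-20 names), the
#' subset of labels flagged as electro-oculogram (EOG) channels, the current
#' reference scheme, stimulus events, and a provenance log that records every
#' operation applied so the preprocessing chain is auditable.
#'
#' Events are stored as a data.frame with columns \code{onset} (0-based sample
#' index), \code{channelType} (\code{"visual"}, \code{"auditory"},
#' \code{"audiovisual"}) and \code{musicType} (\code{"nostalgic"},
#' \code{"non-nostalgic"}). Onsets must be strictly increasing.
#'
#' @slot data numeric matrix, channels x samples, microvolts; rownames are the
#'   channel labels.
#' @slot fs sampling rate in Hz.
#' @slot channelLabels character vector of unique channel labels.
#' @slot eogLabels labels of EOG channels (excluded from scalp analyses).
#' @slot reference reference tag: \code{"average"}, \code{"linked-mastoid"} or
#'   \code{"other"}.
#' @slot events data.frame of stimulus events (see Details).
#' @slot provenance list of log entries, one per applied operation.
#' @export
setClass("EEGRecording",
  representation(
    data = "matrix",
    fs = "numeric",
    channelLabels = "character",
    eogLabels = "character",
    reference = "character",
    events = "data.frame",
    provenance = "list"
  )
)

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (!is.numeric(object@data)) msg <- c(msg, "data must be numeric")
  if (anyNA(object@data)) msg <- c(msg, "data contains NA/NaN")
  if (length(object@fs) != 1L || object@fs <= 0) msg <- c(msg, "fs must be a positive scalar")
  if (nrow(object@data) != length(object@channelLabels))
    msg <- c(msg, "channelLabels length must match nrow(data)")
  if (anyDuplicated(object@channelLabels))
    msg <- c(msg, "channel labels must be unique")
  if (!all(object@eogLabels %in% object@channelLabels))
    msg <- c(msg, "eogLabels must be a subset of channelLabels")
  if (!object@reference %in% c("average", "linked-mastoid", "other"))
    msg <- c(msg, "reference must be one of average/linked-mastoid/other")
  ev <- object@events
  if (nrow(ev)) {
    need <- c("onset", "channelType", "musicType")
    if (!all(need %in% names(ev))) {
      msg <- c(msg, "events needs columns onset/channelType/musicType")
    } else {
      if (is.unsorted(ev$onset, strictly = TRUE))
        msg <- c(msg, "event onsets must be strictly increasing")
      if (any(ev$onset < 0) || any(ev$onset >= ncol(object@data)))
        msg <- c(msg, "event onsets outside recording")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Stimulus-locked epochs
#'
#' Fixed-length stimulus-locked segments cut from a continuous recording,
#' stored as a trials x channels x samples array, with per-trial condition
#' labels, the baseline window used for correction, and a per-trial rejection
#' mask. Rejected trials are excluded from every downstream average.
#'
#' @slot data numeric array, trials x channels x samples, microvolts.
#' @slot fs sampling rate in Hz.
#' @slot channelLabels,eogLabels as in \code{\linkS4class{EEGRecording}}.
#' @slot conditions data.frame with one row per trial (columns
#'   \code{channelType}, \code{musicType}).
#' @slot window numeric length-2, epoch window (t0, t1) in seconds relative to
#'   stimulus onset.
#' @slot baselineWindow numeric length-2, baseline window in seconds relative
#'   to onset (NA if no baseline correction applied yet).
#' @slot rejected logical per-trial rejection mask.
#' @slot provenance list of provenance entries.
#' @export
setClass("EEGEpochs",
  representation(
    data = "array",
    fs = "numeric",
    channelLabels = "character",
    eogLabels = "character",
    conditions = "data.frame",
    window = "numeric",
    baselineWindow = "numeric",
    rejected = "logical",
    provenance = "list"
  )
)

setValidity("EEGEpochs", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L) msg <- c(msg, "data must be a 3-d array (trial x channel x sample)")
  else {
    if (d[2] != length(object@channelLabels))
      msg <- c(msg, "channelLabels length must match dim 2")
    if (nrow(object@conditions) != d[1])
      msg <- c(msg, "conditions must have one row per trial")
    if (length(object@rejected) != d[1])
      msg <- c(msg, "rejected mask must have one entry per trial")
  }
  if (anyNA(object@data)) msg <- c(msg, "epoch data contains NA")
  if (length(msg)) msg else TRUE
})

#' Power spectral density summary
#'
#' Welch power spectral density per channel, with (after
#' \code{\link{bandAggregate}}) band-aggregated absolute power, relative power
#' and electrode-region means.
#'
#' @slot freqs frequency grid in Hz.
#' @slot psd channels x frequencies matrix, uV^2/Hz.
#' @slot bandPower channels x bands matrix, uV^2 (empty until aggregated).
#' @slot relativePower channels x bands matrix, unitless.
#' @slot regionMeans data.frame of region x band mean band power.
#' @slot bands data.frame of band definitions used (name, lo, hi).
#' @slot channelLabels character channel labels.
#' @slot meta list: segment length, overlap, epochs averaged, etc.
#' @export
setClass("SpectralSummary",
  representation(
    freqs = "numeric",
    psd = "matrix",
    bandPower = "matrix",
    relativePower = "matrix",
    regionMeans = "data.frame",
    bands = "data.frame",
    channelLabels = "character",
    meta = "list"
  )
)

setValidity("SpectralSummary", function(object) {
  msg <- character()
  if (any(object@psd < -1e-12)) msg <- c(msg, "psd must be non-negative")
  if (nrow(object@psd) != length(object@channelLabels))
    msg <- c(msg, "psd rows must match channelLabels")
  if (ncol(object@psd) != length(object@freqs))
    msg <- c(msg, "psd columns must match freqs")
  if (length(msg)) msg else TRUE
})

#' Per-segment cross-spectral samples for one frequency band
#'
#' Holds the Hann-windowed per-segment Fourier coefficients of every channel
#' at the frequency bins inside one band. The cross-spectrum of a channel pair
#' (i, j) at bin f in segment s is \code{coef[i, f, s] * Conj(coef[j, f, s])};
#' storing coefficients rather than all pairwise products keeps the Hermitian
#' symmetry S_xy = Conj(S_yx) exact by construction. Use
#' \code{\link{pairSamples}} to extract the samples for one pair.
#'
#' @slot coef complex array, channels x bins x segments.
#' @slot freqs frequencies (Hz) of the retained bins.
#' @slot band data.frame row: band name, lo, hi.
#' @slot channelLabels character labels of the channels decomposed.
#' @slot nSegments number of segments (>= 2 for a defined WPLI).
#' @export
setClass("CrossSpectralSamples",
  representation(
    coef = "array",
    freqs = "numeric",
    band = "data.frame",
    channelLabels = "character",
    nSegments = "integer"
  )
)

setValidity("CrossSpectralSamples", function(object) {
  msg <- character()
  d <- dim(object@coef)
  if (length(d) != 3L) msg <- c(msg, "coef must be channels x bins x segments")
  else {
    if (d[1] != length(object@channelLabels)) msg <- c(msg, "coef rows must match channelLabels")
    if (d[2] != length(object@freqs)) msg <- c(msg, "coef bins must match freqs")
    if (d[3] != object@nSegments) msg <- c(msg, "coef segments must match nSegments")
  }
  if (object@nSegments < 2L) msg <- c(msg, "need >= 2 segments for a defined WPLI")
  if (length(msg)) msg else TRUE
})

#' WPLI functional connectivity matrix
#'
#' Symmetric channel x channel weighted phase lag index matrix for one band
#' and one condition (and one subject, or a group mean). Entries lie in
#' [0, 1]; the diagonal is zero by convention.
#'
#' @slot W numeric matrix, channels x channels.
#' @slot band data.frame row: band name, lo, hi.
#' @slot condition named character, e.g. c(musicType = "nostalgic").
#' @slot subject subject identifier ("" for group means).
#' @slot meta list (n subjects averaged, n segments, 0/0 pairs, ...).
#' @export
setClass("ConnectivityMatrix",
  representation(
    W = "matrix",
    band = "data.frame",
    condition = "character",
    subject = "character",
    meta = "list"
  )
)

setValidity("ConnectivityMatrix", function(object) {
  msg <- character()
  W <- object@W
  if (nrow(W) != ncol(W)) msg <- c(msg, "W must be square")
  else {
    if (max(abs(W - t(W))) > 1e-9) msg <- c(msg, "W must be symmetric")
    if (any(abs(diag(W)) > 1e-12)) msg <- c(msg, "diagonal must be zero")
    if (any(W < -1e-12) || any(W > 1 + 1e-9)) msg <- c(msg, "entries must lie in [0,1]")
  }
  if (length(msg)) msg else TRUE
})

#' Weighted brain-network metrics
#'
#' Node strength, Onnela clustering coefficient, characteristic path length,
#' global and local efficiency of one weighted network, with the conventions
#' used (distance rule, clustering normalization, unreachable-pair handling)
#' recorded in \code{meta}.
#'
#' @slot strength per-node strength (sum of edge weights).
#' @slot meanStrength network-level connection strength (mean node strength).
#' @slot clustering per-node Onnela clustering coefficient.
#' @slot meanClustering mean clustering.
#' @slot charPathLength mean shortest-path distance over reachable ordered
#'   pairs (edge length = 1/weight).
#' @slot nUnreachable count of unreachable ordered pairs excluded from
#'   \code{charPathLength} (they contribute 0 to efficiency).
#' @slot globalEfficiency mean inverse shortest-path distance.
#' @slot localEfficiency mean over nodes of neighborhood-subgraph global
#'   efficiency.
#' @slot meta list: band/condition/subject metadata and conventions.
#' @export
setClass("NetworkMetrics",
  representation(
    strength = "numeric",
    meanStrength = "numeric",
    clustering = "numeric",
    meanClustering = "numeric",
    charPathLength = "numeric",
    nUnreachable = "integer",
    globalEfficiency = "numeric",
    localEfficiency = "numeric",
    meta = "list"
  )
)

#' Simulation configuration
#'
#' Parameters of the synthetic EEG study: montage size, sampling rate, trial
#' structure, per-band condition-dependent coupling strengths, noise and
#' artifact levels, and the behavioral rating calibration. The defaults
#' (see \code{\link{simConfig}}) reproduce the study conditions: a 3
#' (sensory channel: visual, auditory, audiovisual) x 2 (music type:
#' nostalgic, non-nostalgic) within-subject design with 5 trials per cell,
#' 30 s stimuli, 64-channel extended 10-20 montage at 500 Hz.
#'
#' @slot nSubjects number of subjects.
#' @slot nChannels number of scalp channels (<= 64, taken from the standard
#'   montage in order).
#' @slot fs sampling rate, Hz; must exceed twice the highest coupled band edge.
#' @slot trialSec stimulus duration, seconds.
#' @slot baselineSec pre-stimulus fixation, seconds.
#' @slot gapSec post-trial blank, seconds.
#' @slot nTrialsPerCell trials per (channelType, musicType) cell.
#' @slot bandCoupling named list: band name -> named numeric coupling strength
#'   g in [0,1] per music type, e.g. list(alpha = c(nostalgic = 0.8,
#'   "non-nostalgic" = 0.3)).
#' @slot couplingFraction fraction of scalp channels receiving the shared
#'   narrowband source.
#' @slot noiseSd background pink-noise standard deviation, uV.
#' @slot blinkRate blinks per minute.
#' @slot lineNoiseUv 50 Hz line-noise amplitude, uV.
#' @slot spikeProb probability that a trial contains a high-amplitude
#'   movement spike.
#' @slot behaviorMeans data.frame (scale, channelType, musicType, mean, sd)
#'   on the 1-9 Likert grid.
#' @slot seed integer master seed.
#' @export
setClass("SimulationConfig",
  representation(
    nSubjects = "integer",
    nChannels = "integer",
    fs = "numeric",
    trialSec = "numeric",
    baselineSec = "numeric",
    gapSec = "numeric",
    nTrialsPerCell = "integer",
    bandCoupling = "list",
    couplingFraction = "numeric",
    noiseSd = "numeric",
    blinkRate = "numeric",
    lineNoiseUv = "numeric",
    spikeProb = "numeric",
    behaviorMeans = "data.frame",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nSubjects < 1L) msg <- c(msg, "need at least one subject")
  if (object@nChannels < 4L || object@nChannels > 64L)
    msg <- c(msg, "nChannels must be in [4, 64]")
  if (object@nTrialsPerCell < 1L) msg <- c(msg, "need at least one trial per cell")
  if (object@trialSec <= 0) msg <- c(msg, "trialSec must be positive")
  bt <- canonicalBands()
  for (bn in names(object@bandCoupling)) {
    g <- object@bandCoupling[[bn]]
    if (!bn %in% bt$name) msg <- c(msg, sprintf("unknown band '%s'", bn))
    else if (object@fs <= 2 * bt$hi[bt$name == bn])
      msg <- c(msg, sprintf("fs=%g violates Nyquist for band '%s' (hi=%g Hz)",
                            object@fs, bn, bt$hi[bt$name == bn]))
    if (any(g < 0) || any(g > 1)) msg <- c(msg, "coupling strengths must lie in [0,1]")
    if (!all(c("nostalgic", "non-nostalgic") %in% names(g)))
      msg <- c(msg, sprintf("band '%s' coupling needs nostalgic and non-nostalgic entries", bn))
  }
  bm <- object@behaviorMeans
  if (nrow(bm)) {
    if (any(bm$mean < 1) || any(bm$mean > 9))
      msg <- c(msg, "behavior means must lie on the 1-9 Likert grid")
    if (any(bm$sd < 0)) msg <- c(msg, "behavior sds must be non-negative")
  }
  if (length(msg)) msg else TRUE
})
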