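#' Default behavioral calibration table
#'
#' Cell means and standard deviations, on the 1-9 Likert grid, for the four
#' rating scales (state nostalgia, pleasure, arousal, dominance) in each of
#' the six (channelType x musicType) design cells. Values follow the study's
#' descriptive statistics: the emotional-response cells use the published
#' per-cell mean +/- SD table; the state-nostalgia cells use the
#' simple-effect cell means (the manipulation-check table prints slightly
#' different means for the same cells — an internal inconsistency of the
#' source; the simple-effect set is used because it is the one the
#' interaction analysis is anchored to), with the manipulation-check SDs, the
#' only per-cell SDs printed for that scale.
#'
#' @return data.frame with columns \code{scale}, \code{channelType},
#'   \code{musicType}, \code{mean}, \code{sd}.
#' @export
defaultBehaviorMeans <- function() {
  ch <- c("auditory", "visual", "audiovisual")
  cell <- function(scale, music, means, sds) {
    data.frame(scale = scale, channelType = ch, musicType = music,
               mean = means, sd = sds, stringsAsFactors = FALSE)
  }
  rbind(
    cell("nostalgia", "nostalgic",     c(7.65, 7.35, 7.79), c(0.88, 0.95, 0.65)),
    cell("nostalgia", "non-nostalgic", c(3.86, 3.29, 3.80), c(1.81, 1.57, 1.80)),
    cell("pleasure",  "nostalgic",     c(7.132, 6.991, 7.192), c(1.002, 0.84, 0.986)),
    cell("pleasure",  "non-nostalgic", c(4.916, 4.57, 5.209), c(0.86, 0.928, 0.648)),
    cell("arousal",   "nostalgic",     c(7.114, 6.877, 7.209), c(0.94, 1.115, 1.063)),
    cell("arousal",   "non-nostalgic", c(4.937, 4.507, 4.798), c(1.069, 0.984, 1.183)),
    cell("dominance", "nostalgic",     c(7.13, 6.84, 7.344), c(1.308, 1.491, 1.301)),
    cell("dominance", "non-nostalgic", c(6.402, 6.0, 6.486), c(1.515, 1.809, 1.616))
  )
}

#' Default per-band condition coupling
#'
#' Phase-lagged coupling strengths g in [0, 1] per band and music type. The
#' defaults plant the study's qualitative headline: elevated alpha- and
#' gamma-band coupling under nostalgic stimulation, equal (null) coupling in
#' theta and beta, no planted delta coupling.
#'
#' @return named list of named numeric vectors.
#' @export
defaultBandCoupling <- function() {
  list(
    theta = c(nostalgic = 0.4, "non-nostalgic" = 0.4),
    alpha = c(nostalgic = 0.8, "non-nostalgic" = 0.3),
    beta  = c(nostalgic = 0.4, "non-nostalgic" = 0.4),
    gamma = c(nostalgic = 0.8, "non-nostalgic" = 0.3)
  )
}

#' Build a simulation configuration
#'
#' Constructor with the study conditions as defaults: 38 subjects, 64-channel
#' extended 10-20 montage at 500 Hz, 30 s stimuli preceded by a 5 s fixation
#' baseline and followed by a 3 s blank, 5 trials per (sensory channel x
#' music type) cell presented in visual / auditory / audiovisual block order,
#' condition-dependent phase-lagged band coupling
#' (\code{\link{defaultBandCoupling}}), pink background noise, and blink /
#' line-noise / movement-spike artifacts. All sizes are configurable so the
#' generator can be run at reduced scale.
#'
#' @param nSubjects,nChannels,fs,trialSec,baselineSec,gapSec,nTrialsPerCell
#'   see \code{\linkS4class{SimulationConfig}}.
#' @param bandCoupling named list band -> c(nostalgic=, "non-nostalgic"=).
#' @param couplingFraction fraction of scalp channels carrying the shared
#'   source (default 0.5).
#' @param noiseSd pink-noise SD in uV (default 10).
#' @param blinkRate blinks per minute (default 15; 0 disables).
#' @param lineNoiseUv 50 Hz line-noise amplitude in uV (default 2; applied
#'   only when fs resolves 50 Hz).
#' @param spikeProb per-trial probability of a high-amplitude movement spike
#'   (default 0.05).
#' @param behaviorMeans calibration table, default
#'   \code{\link{defaultBehaviorMeans}}.
#' @param seed master seed.
#' @return a validated \code{\linkS4class{SimulationConfig}}.
#' @export
#' @examples
#' cfg <- simConfig(nSubjects = 2, nChannels = 8, fs = 128, trialSec = 4,
#'                  nTrialsPerCell = 1, seed = 1)
#' cfg
simConfig <- function(nSubjects = 38L, nChannels = 64L, fs = 500,
                      trialSec = 30, baselineSec = 5, gapSec = 3,
                      nTrialsPerCell = 5L,
                      bandCoupling = defaultBandCoupling(),
                      couplingFraction = 0.5,
                      noiseSd = 10, blinkRate = 15, lineNoiseUv = 2,
                      spikeProb = 0.05,
                      behaviorMeans = defaultBehaviorMeans(),
                      seed = 1L) {
  new("SimulationConfig",
      nSubjects = as.integer(nSubjects), nChannels = as.integer(nChannels),
      fs = fs, trialSec = trialSec, baselineSec = baselineSec,
      gapSec = gapSec, nTrialsPerCell = as.integer(nTrialsPerCell),
      bandCoupling = bandCoupling, couplingFraction = couplingFraction,
      noiseSd = noiseSd, blinkRate = blinkRate, lineNoiseUv = lineNoiseUv,
      spikeProb = spikeProb, behaviorMeans = behaviorMeans,
      seed = as.integer(seed))
}

#' Channels carrying the shared narrowband source
#'
#' The deterministic subset of scalp channels into which the simulator mixes
#' the per-band common source: the first
#' \code{ceiling(couplingFraction * nChannels)} montage channels.
#'
#' @param config a \code{\linkS4class{SimulationConfig}}.
#' @return character vector of channel labels.
#' @export
coupledChannels <- function(config) {
  labs <- standardMontage(config@nChannels)$label
  labs[seq_len(max(2L, ceiling(config@couplingFraction * config@nChannels)))]
}
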