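#' Simulate one subject's continuous EEG recording
#'
#' Generates a continuous multichannel recording covering the full trial
#' sequence in block order (visual, then auditory, then audiovisual; within a
#' block, nostalgic and non-nostalgic trials are randomly interleaved). Each
#' scalp channel carries unit-shape pink (1/f) background noise scaled to
#' \code{noiseSd}. During each trial, for every band with configured
#' coupling, a shared band-limited source is mixed into the coupled channel
#' subset (\code{\link{coupledChannels}}) at strength \code{g(band,
#' musicType)}; each coupled channel applies its own phase offset, drawn once
#' per subject with magnitude uniform in (pi/4, pi/2) and alternating sign
#' across the subset, so phase-lag signs are consistent over time and the
#' planted WPLI is high. Blink, 50 Hz line-noise and movement-spike artifacts
#' are injected per the artifact settings; blinks are also written to the
#' simulated VEOG/HEOG channels so ICA-based removal is testable.
#'
#' The output is bit-identical for identical \code{(config, subjectId)}: all
#' randomness derives from \code{config@seed} and the subject index.
#'
#' @param config a \code{\linkS4class{SimulationConfig}}.
#' @param subjectId 0-based subject index (< \code{nSubjects}).
#' @return a list with elements \code{recording}
#'   (\code{\linkS4class{EEGRecording}}, with events attached) and
#'   \code{truth} (list: blink onset samples and amplitudes, spike trials,
#'   per-channel phase offsets) for verification against ground truth.
#' @export
#' @examples
#' cfg <- simConfig(nSubjects = 1, nChannels = 8, fs = 128, trialSec = 4,
#'                  baselineSec = 1, gapSec = 0.5, nTrialsPerCell = 1,
#'                  blinkRate = 0, spikeProb = 0, seed = 7)
#' rec <- makeSubjectRecording(cfg, 0)$recording
#' rec
makeSubjectRecording <- function(config, subjectId) {
  validObject(config)
  stopifnot(subjectId >= 0, subjectId < config@nSubjects)
  withSeed(deriveSeed(config@seed, 101L, subjectId), {
    fs <- config@fs
    nCh <- config@nChannels
    scalp <- standardMontage(nCh)$label
    eog <- c("VEOG", "HEOG")
    labels <- c(scalp, eog)

    trialLen <- round(config@trialSec * fs)
    slotLen <- round((config@baselineSec + config@trialSec + config@gapSec) * fs)
    pad <- round(2 * fs)
    chTypes <- c("visual", "auditory", "audiovisual")
    perBlock <- 2L * config@nTrialsPerCell
    nTrials <- 3L * perBlock
    n <- 2L * pad + nTrials * slotLen

    # trial table in block order, music types shuffled within block
    music <- unlist(lapply(seq_along(chTypes), function(b)
      sample(rep(c("nostalgic", "non-nostalgic"), config@nTrialsPerCell))))
    events <- data.frame(
      onset = as.integer(pad + (seq_len(nTrials) - 1L) * slotLen +
        round(config@baselineSec * fs)),
      channelType = rep(chTypes, each = perBlock),
      musicType = music,
      stringsAsFactors = FALSE
    )

    data <- matrix(0, nrow = length(labels), ncol = n,
                   dimnames = list(labels, NULL))
    for (i in seq_along(scalp)) data[i, ] <- config@noiseSd * pinkNoise(n, fs)
    for (lab in eog) data[lab, ] <- 5 * pinkNoise(n, fs)

    # per-subject phase offsets: alternating sign, magnitude in (pi/4, pi/2)
    coupled <- coupledChannels(config)
    coupled <- coupled[coupled %in% scalp]
    m <- length(coupled)
    phase <- list()
    bt <- canonicalBands()
    for (bn in names(config@bandCoupling)) {
      mag <- runif(m, pi / 4, pi / 2)
      phase[[bn]] <- mag * rep_len(c(1, -1), m)
    }

    # condition-dependent band-limited coupling during trials
    srcAmp <- config@noiseSd
    for (t in seq_len(nTrials)) {
      idx <- events$onset[t] + seq_len(trialLen)
      for (bn in names(config@bandCoupling)) {
        g <- config@bandCoupling[[bn]][[events$musicType[t]]]
        if (g <= 0) next
        b <- bt[bt$name == bn, ]
        z <- narrowbandSource(trialLen, fs, b$lo, b$hi)
        for (k in seq_len(m)) {
          ch <- coupled[k]
          data[ch, idx] <- data[ch, idx] +
            g * srcAmp * Re(z * exp(1i * phase[[bn]][k]))
        }
      }
    }

    # artifacts ---------------------------------------------------------
    truth <- list(phase = phase, coupled = coupled,
                  blinkOnsets = integer(0), blinkAmps = numeric(0),
                  spikeTrials = integer(0))
    if (config@blinkRate > 0) {
      nBlinks <- rpois(1, config@blinkRate * n / fs / 60)
      blinkLen <- round(0.4 * fs)
      tmpl <- hannWindow(blinkLen)^2
      if (nBlinks > 0) {
        onsets <- sort(sample.int(n - blinkLen, nBlinks))
        amps <- rnorm(nBlinks, 120, 15)
        w <- blinkWeights(labels)
        w[labels == "VEOG"] <- 2
        w[labels == "HEOG"] <- 0.3
        for (bI in seq_len(nBlinks)) {
          seg <- onsets[bI] + seq_len(blinkLen)
          data[, seg] <- data[, seg] + outer(w * amps[bI], tmpl)
        }
        truth$blinkOnsets <- onsets
        truth$blinkAmps <- amps
      }
    }
    if (config@lineNoiseUv > 0 && fs > 100) {
      tt <- seq_len(n) / fs
      ln <- config@lineNoiseUv * sin(2 * pi * 50 * tt + runif(1, 0, 2 * pi))
      data <- data + matrix(ln, nrow = nrow(data), ncol = n, byrow = TRUE)
    }
    if (config@spikeProb > 0) {
      spikeLen <- max(3L, round(0.05 * fs))
      for (t in seq_len(nTrials)) {
        if (rbinom(1, 1, config@spikeProb) == 1L) {
          ch <- sample(seq_along(scalp), 1)
          at <- events$onset[t] + sample.int(trialLen - spikeLen, 1)
          data[ch, at + seq_len(spikeLen)] <- data[ch, at + seq_len(spikeLen)] +
            runif(1, 140, 180) * hannWindow(spikeLen)
          truth$spikeTrials <- c(truth$spikeTrials, t)
        }
      }
    }

    rec <- new("EEGRecording", data = data, fs = fs, channelLabels = labels,
               eogLabels = eog, reference = "average", events = events,
               provenance = list(list(
                 op = "simulate",
                 params = list(subjectId = subjectId, seed = config@seed,
                               nBlinks = length(truth$blinkOnsets),
                               spikeTrials = truth$spikeTrials))))
    list(recording = rec, truth = truth)
  })
}

#' Reconstruct the planted blink time course
#'
#' Rebuilds the unit-amplitude blink regressor (sum of the stereotyped
#' 0.4 s blink templates at their planted onsets) from a simulation truth
#' record, for checking ocular-artifact removal against ground truth.
#'
#' @param truth the \code{truth} element returned by
#'   \code{\link{makeSubjectRecording}}.
#' @param n recording length in samples.
#' @param fs sampling rate, Hz.
#' @return numeric vector of length \code{n}.
#' @export
blinkTimecourse <- function(truth, n, fs) {
  x <- numeric(n)
  blinkLen <- round(0.4 * fs)
  tmpl <- hannWindow(blinkLen)^2
  for (i in seq_along(truth$blinkOnsets)) {
    seg <- truth$blinkOnsets[i] + seq_len(blinkLen)
    x[seg] <- x[seg] + truth$blinkAmps[i] * tmpl
  }
  x
}
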