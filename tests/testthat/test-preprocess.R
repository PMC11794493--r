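# Filtering, interpolation, re-referencing, epoching and rejection.

toneRec <- function(freqs, amps = rep(1, length(freqs)), fs = 500, dur = 10,
                    nCh = 1) {
  tt <- seq_len(fs * dur) / fs
  x <- Reduce(`+`, Map(function(f, a) a * sin(2 * pi * f * tt), freqs, amps))
  matrixRecording(matrix(rep(x, nCh), nrow = nCh, byrow = TRUE), fs)
}

toneAmp <- function(rec, freq, ch = 1) {
  # amplitude of a pure tone via the analytic envelope, ignoring filter edges
  x <- channelData(rec)[ch, ]
  edge <- round(length(x) * 0.2)
  mid <- x[edge:(length(x) - edge)]
  sqrt(2 * mean(mid^2))
}

test_that("band-pass removes DC, preserves mid-band tones, kills out-of-band tones", {
  rec <- matrixRecording(matrix(5, 1, 5000), 500)
  out <- bandpassFilter(rec, 0.1, 50)
  expect_lt(max(abs(channelData(out))), 1e-6 * 5)

  rec10 <- toneRec(10)
  expect_equal(toneAmp(bandpassFilter(rec10, 0.1, 50), 10), 1, tolerance = 0.01)

  rec80 <- toneRec(80)
  out80 <- bandpassFilter(rec80, 0.1, 50)
  expect_lt(toneAmp(out80, 80), 10^(-20 / 20))   # >= 20 dB down

  expect_error(bandpassFilter(rec10, 0.1, 300), "Nyquist")
  expect_error(bandpassFilter(rec10, 50, 10))
})

test_that("notch attenuates 50 Hz >= 20 dB, leaves 10 Hz intact, is linear", {
  rec50 <- toneRec(50)
  expect_lt(toneAmp(notchFilter(rec50), 50), 0.1)

  rec10 <- toneRec(10)
  expect_equal(toneAmp(notchFilter(rec10), 10), 1, tolerance = 0.01)

  both <- toneRec(c(10, 50))
  out <- notchFilter(both)
  ref <- channelData(rec10)[1, ]
  got <- channelData(out)[1, ]
  edge <- 1000
  mid <- edge:(length(ref) - edge)
  expect_lt(sqrt(mean((got[mid] - ref[mid])^2)) / sqrt(mean(ref[mid]^2)), 0.02)
})

test_that("filters are zero-phase: no lag on a mid-band tone", {
  rec <- toneRec(10)
  out <- bandpassFilter(rec, 1, 40)
  x <- channelData(rec)[1, ]; y <- channelData(out)[1, ]
  cc <- ccf(x, y, lag.max = 25, plot = FALSE)
  expect_equal(as.numeric(cc$lag[which.max(cc$acf)]), 0)
})

test_that("interpolation: identity on empty set, recovery of a corrupted copy, locality", {
  cfg <- tinyCfg(nChannels = 16, trialSec = 3, seed = 9)
  rec <- makeSubjectRecording(cfg, 0)$recording
  expect_identical(channelData(interpolateBad(rec, character(0))),
                   channelData(rec))

  # spatially coherent field: shared source plus small channel noise, with
  # the target channel planted as an exact copy of a neighbor, then
  # corrupted; interpolation must recover the copy
  set.seed(9)
  fs <- 128; n <- fs * 10
  labels <- standardMontage(16)$label
  common <- wpliNet:::pinkNoise(n, fs)
  mat <- t(vapply(labels, function(l) common + 0.15 * rnorm(n), numeric(n)))
  target <- "FC1"
  mat[match(target, labels), ] <- mat[match("C3", labels), ]   # planted copy
  original <- mat[match(target, labels), ]
  mat[match(target, labels), ] <- rnorm(n, sd = 5)             # corrupted
  rec2 <- matrixRecording(mat, fs, labels = labels)
  fixed <- interpolateBad(rec2, target)
  expect_gt(cor(channelData(fixed)[target, ], original), 0.9)
  others <- setdiff(labels, target)
  expect_identical(channelData(fixed)[others, ], channelData(rec2)[others, ])

  expect_error(interpolateBad(rec, "NoSuchChannel"), "unknown")
  expect_error(interpolateBad(rec2, labels[1:14]), "at least 4")
})

test_that("linked-mastoid re-referencing follows its definition and is idempotent", {
  cfg <- tinyCfg(nChannels = 24, trialSec = 2, seed = 14)
  rec <- makeSubjectRecording(cfg, 0)$recording
  out <- rereferenceLinkedMastoids(rec)
  ref <- colMeans(channelData(rec)[c("TP9", "TP10"), ])
  for (ch in c("Fp1", "TP9", "Cz")) {
    expect_equal(channelData(out)[ch, ], channelData(rec)[ch, ] - ref,
                 tolerance = 1e-12)
  }
  expect_identical(out@reference, "linked-mastoid")
  # EOG channels are left untouched
  expect_identical(channelData(out)["VEOG", ], channelData(rec)["VEOG", ])

  # zero mastoids: identity
  rec0 <- rec
  rec0@data["TP9", ] <- 0; rec0@data["TP10", ] <- 0
  out0 <- rereferenceLinkedMastoids(rec0)
  expect_equal(channelData(out0), channelData(rec0), tolerance = 1e-12)

  # after re-referencing, the mastoid pair is mutually opposite, so a second
  # application subtracts zero
  out2 <- rereferenceLinkedMastoids(out)
  expect_equal(channelData(out2), channelData(out), tolerance = 1e-9)

  # M1/M2 synonyms resolve; missing labels raise a labeled error
  expect_equal(channelData(rereferenceLinkedMastoids(rec, c("M1", "M2"))),
               channelData(out), tolerance = 1e-12)
  small <- makeSubjectRecording(tinyCfg(nChannels = 8, trialSec = 2), 0)$recording
  expect_error(rereferenceLinkedMastoids(small), "not found")
})

test_that("epoching: constant channels zero out, sample counts are exact, order-invariant", {
  fs <- 500
  n <- fs * 120
  mat <- rbind(rep(3, n), sin(2 * pi * 7 * seq_len(n) / fs))
  events <- data.frame(onset = c(2500L, 40000L),
                       channelType = c("visual", "auditory"),
                       musicType = c("nostalgic", "non-nostalgic"),
                       stringsAsFactors = FALSE)
  rec <- matrixRecording(mat, fs, events = events)
  ep <- epochAndBaseline(rec, t0 = 0, t1 = 30, baseline = c(-5, 0))
  expect_identical(dim(channelData(ep)), c(2L, 2L, 15000L))
  expect_lt(max(abs(channelData(ep)[, 1, ])), 1e-12)

  shuffled <- events[c(2, 1), ]
  # onsets must be increasing in the container, so re-sort to compare content
  ep2 <- epochAndBaseline(rec, events = shuffled, t0 = 0, t1 = 30,
                          baseline = c(-5, 0))
  i1 <- order(conditions(ep)$musicType)
  i2 <- order(conditions(ep2)$musicType)
  expect_equal(channelData(ep)[i1, , ], channelData(ep2)[i2, , ])

  # out-of-range trial dropped with a warning, not a failure
  badEvents <- rbind(events,
                     data.frame(onset = n - 100L, channelType = "audiovisual",
                                musicType = "nostalgic"))
  expect_warning(ep3 <- epochAndBaseline(rec, events = badEvents, t0 = 0,
                                         t1 = 30, baseline = c(-5, 0)),
                 "dropped")
  expect_identical(dim(channelData(ep3))[1], 2L)
})

test_that("amplitude rejection: strict threshold, planted spikes, EOG exempt", {
  fs <- 100
  mk <- function(peaks) {
    arr <- array(0, dim = c(length(peaks), 2, 100))
    for (i in seq_along(peaks)) arr[i, 1, 50] <- peaks[i]
    new("EEGEpochs", data = arr, fs = fs,
        channelLabels = c("Cz", "VEOG"), eogLabels = "VEOG",
        conditions = data.frame(channelType = rep("visual", length(peaks)),
                                musicType = rep("nostalgic", length(peaks))),
        window = c(0, 1), baselineWindow = c(NA_real_, NA_real_),
        rejected = logical(length(peaks)), provenance = list())
  }
  ep <- rejectAmplitude(mk(c(75.1, 74.9, -80, 75.0)))
  expect_identical(rejectedMask(ep), c(TRUE, FALSE, TRUE, FALSE))
  expect_identical(rejectedMask(rejectAmplitude(mk(c(200, 300)), Inf)),
                   c(FALSE, FALSE))

  # an EOG excursion alone never rejects
  epEog <- mk(c(10, 10))
  epEog@data[1, 2, 10] <- 500
  expect_identical(rejectedMask(rejectAmplitude(epEog)), c(FALSE, FALSE))

  # simulator-planted spikes are rejected trial-for-trial
  cfg <- tinyCfg(nChannels = 6, trialSec = 3, nTrialsPerCell = 3,
                 seed = 77, noiseSd = 3, spikeProb = 0.5)
  sim <- makeSubjectRecording(cfg, 0)
  ep2 <- epochAndBaseline(sim$recording, t0 = 0, t1 = 3, baseline = c(-1, 0))
  ep2 <- rejectAmplitude(ep2)
  expect_gt(length(sim$truth$spikeTrials), 0)
  expect_identical(which(rejectedMask(ep2)), as.integer(sim$truth$spikeTrials))
  expect_error(retainedTrials(ep2, musicType = "no-such"), "no retained")
})

test_that("operations never mutate inputs and append provenance entries", {
  cfg <- tinyCfg(nChannels = 6, trialSec = 2, seed = 3)
  rec <- makeSubjectRecording(cfg, 0)$recording
  before <- channelData(rec)
  out <- notchFilter(bandpassFilter(rec, 1, 45), 20, 25)
  expect_identical(channelData(rec), before)
  ops <- vapply(provenance(out), `[[`, "", "op")
  expect_identical(ops, c("simulate", "bandpass", "notch"))
})
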