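# The synthetic-data generator: determinism, planted coupling structure,
# null behavior, and the behavioral calibration.

test_that("identical (config, subject) gives bit-identical recordings and tables", {
  cfg <- tinyCfg(seed = 5, blinkRate = 10, spikeProb = 0.2, lineNoiseUv = 2)
  r1 <- makeSubjectRecording(cfg, 0)
  r2 <- makeSubjectRecording(cfg, 0)
  expect_identical(channelData(r1$recording), channelData(r2$recording))
  expect_identical(r1$truth, r2$truth)
  # different subjects differ
  r3 <- makeSubjectRecording(cfg, 1)
  expect_false(identical(channelData(r1$recording), channelData(r3$recording)))
  expect_identical(generateBehavior(cfg), generateBehavior(cfg))
})

test_that("recording layout follows the block design", {
  cfg <- tinyCfg(nTrialsPerCell = 2, seed = 8)
  rec <- makeSubjectRecording(cfg, 0)$recording
  ev <- conditions(rec)
  expect_identical(ev$channelType,
                   rep(c("visual", "auditory", "audiovisual"), each = 4))
  expect_identical(unname(table(ev$musicType, ev$channelType)["nostalgic", ]),
                   rep(2L, 3))
  expect_true(all(diff(ev$onset) >= cfg@trialSec * cfg@fs))
  expect_identical(eogLabels(rec), c("VEOG", "HEOG"))
})

test_that("planted alpha coupling yields higher nostalgic WPLI in nearly all subjects", {
  cfg <- tinyCfg(nSubjects = 12, nChannels = 8, trialSec = 5,
                 nTrialsPerCell = 2, seed = 42)
  cc <- coupledChannels(cfg)
  diffs <- vapply(seq_len(cfg@nSubjects) - 1L, function(s) {
    rec <- makeSubjectRecording(cfg, s)$recording
    ep <- epochAndBaseline(rec, t0 = 0, t1 = 5, baseline = c(-1, 0))
    a <- meanConnectivity(wpliMatrix(ep, "alpha", musicType = "nostalgic",
                                     channels = cc))
    b <- meanConnectivity(wpliMatrix(ep, "alpha", musicType = "non-nostalgic",
                                     channels = cc))
    a - b
  }, 0)
  expect_gte(sum(diffs > 0), 11)   # >= 11/12 subjects, cf. 19/20
})

test_that("with no coupling, pairwise WPLI stays low given 30 s of data", {
  cfg <- tinyCfg(nSubjects = 1, nChannels = 4, trialSec = 10,
                 nTrialsPerCell = 1,
                 bandCoupling = list(alpha = c(nostalgic = 0,
                                               "non-nostalgic" = 0)),
                 seed = 31)
  vals <- unlist(lapply(1:10, function(r) {
    cfg@seed <- 31L + r
    rec <- makeSubjectRecording(cfg, 0)$recording
    ep <- epochAndBaseline(rec, t0 = 0, t1 = 10, baseline = NULL)
    W <- connMatrix(wpliMatrix(ep, "alpha"))   # 30 s pooled over 3 trials
    W[upper.tri(W)]
  }))
  expect_lt(mean(vals), 0.2)
  expect_lt(quantile(vals, 0.9), 0.35)
})

test_that("mean WPLI of the coupled subset is monotone in the coupling strength", {
  gs <- c(0, 0.3, 0.6, 0.9)
  means <- vapply(gs, function(g) {
    mean(vapply(1:5, function(r) {
      cfg <- tinyCfg(nSubjects = 1, nChannels = 6, trialSec = 5,
                     nTrialsPerCell = 2,
                     bandCoupling = list(alpha = c(nostalgic = g,
                                                   "non-nostalgic" = g)),
                     seed = 500 + r)
      rec <- makeSubjectRecording(cfg, 0)$recording
      ep <- epochAndBaseline(rec, t0 = 0, t1 = 5, baseline = NULL)
      meanConnectivity(wpliMatrix(ep, "alpha",
                                  channels = coupledChannels(cfg)))
    }, 0))
  }, 0)
  expect_true(all(diff(means) > -0.02))  # non-decreasing within MC error
  expect_gt(means[4], means[1] + 0.2)    # and clearly increasing overall
})

test_that("ratings respect the Likert grid and the configured calibration", {
  cfg <- simConfig(nSubjects = 38, seed = 7)
  b <- generateBehavior(cfg)
  for (sc in c("nostalgia", "pleasure", "arousal", "dominance")) {
    expect_true(all(b[[sc]] >= 1 & b[[sc]] <= 9))
    expect_true(all(b[[sc]] == round(b[[sc]])))
  }
  # cell calibrated to 7.132 +/- 1.002: sample mean within 0.25
  cell <- b$pleasure[b$channel_type == "auditory" & b$music_type == "nostalgic"]
  expect_length(cell, 38 * 5)
  expect_lt(abs(mean(cell) - 7.132), 0.25)

  # zero noise: every rating equals the rounded cell mean
  bm0 <- defaultBehaviorMeans()
  bm0$sd <- 0
  cfg0 <- simConfig(nSubjects = 3, behaviorMeans = bm0, seed = 1)
  b0 <- generateBehavior(cfg0)
  cell0 <- b0$arousal[b0$channel_type == "visual" & b0$music_type == "nostalgic"]
  expect_true(all(cell0 == round(6.877)))

  # two seeds: different draws, identical schema
  b2 <- generateBehavior(simConfig(nSubjects = 38, seed = 8))
  expect_identical(names(b), names(b2))
  expect_identical(dim(b), dim(b2))
  expect_false(identical(b$pleasure, b2$pleasure))
})

test_that("invalid configurations are rejected", {
  expect_error(tinyCfg(fs = 64,
                       bandCoupling = list(gamma = c(nostalgic = 0.5,
                                                     "non-nostalgic" = 0.5))),
               "Nyquist")
  expect_error(tinyCfg(bandCoupling = list(alpha = c(nostalgic = 1.2,
                                                     "non-nostalgic" = 0))),
               "\\[0,1\\]")
  expect_error(tinyCfg(nTrialsPerCell = 0), "at least one trial")
  bm <- defaultBehaviorMeans()
  bm$mean[1] <- 9.7
  expect_error(simConfig(behaviorMeans = bm), "Likert")
  bm2 <- defaultBehaviorMeans()[-1, ]
  expect_error(generateBehavior(simConfig(behaviorMeans = bm2)), "missing cells")
})
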