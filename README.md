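# wpliNet

Functional brain networks from multichannel EEG, for within-subject designs
that contrast emotional conditions — specifically the 3 (sensory channel:
visual, auditory, audiovisual) × 2 (music type: nostalgic, non-nostalgic)
paradigm used to study music-evoked nostalgia. The package takes continuous
recordings (or simulates them), produces per-band weighted phase lag index
(WPLI) connectivity matrices, weighted graph metrics, band-power spectra,
and the behavioral and neural statistics, as tested, reproducible R code.

## Who it is for

Researchers analyzing sensor-level EEG connectivity under repeated-measures
designs, and anyone who needs a verifiable reference implementation of the
WPLI → graph-metric → paired-statistics chain. Because raw data for this
kind of study are rarely deposited, a synthetic-data generator with planted,
condition-dependent phase-lagged coupling is part of the package: every
stage can be validated against ground truth.

## The statistic at the core

For channels *x*, *y* with cross-spectrum *S<sub>xy</sub>* estimated over
Hann-windowed segments,

&nbsp;&nbsp;&nbsp;&nbsp;WPLI = | E[ Im *S<sub>xy</sub>* ] | / E[ | Im *S<sub>xy</sub>* | ]

— the magnitude-weighted consistency of the phase-lag sign. Zero-lag
(volume-conducted) mixing has Im *S* = 0 and cannot inflate it. Channel ×
channel WPLI matrices are analyzed as full weighted graphs: node strength
*s<sub>i</sub>* = Σ<sub>j</sub> w<sub>ij</sub>, Onnela clustering,
characteristic path length *L* and global/local efficiency under the edge
length ℓ = 1/w. Behavioral ratings get paired *t* tests and a 3 × 2
repeated-measures ANOVA with Greenhouse–Geisser correction
(ε = (Σλ)²/(d·Σλ²)) and partial η².

## Worked example

Simulate a small 8-subject study (12 channels, 128 Hz, 4 s trials), run the
preprocessing chain, and contrast alpha-band networks between music types:

```r
library(wpliNet)

cfg <- simConfig(nSubjects = 8, nChannels = 12, fs = 128, trialSec = 4,
                 baselineSec = 1, gapSec = 0.5, nTrialsPerCell = 2, seed = 42)
rows <- list()
for (s in seq_len(cfg@nSubjects) - 1L) {
  rec <- makeSubjectRecording(cfg, s)$recording
  rec <- notchFilter(bandpassFilter(rec, 0.1, 50), 49, 51)
  ep  <- epochAndBaseline(rec, t0 = 0, t1 = 4, baseline = c(-1, 0))
  ep  <- removeOcularICA(ep, minSec = 30)$epochs
  ep  <- rejectAmplitude(ep, 75)
  for (mt in c("nostalgic", "non-nostalgic")) {
    cm  <- wpliMatrix(ep, "alpha", musicType = mt, subject = as.character(s))
    row <- metricsRow(networkSummary(cm))
    row$subject <- s; row$condition <- mt
    row$mean_wpli <- meanConnectivity(cm)
    rows[[paste(s, mt)]] <- row
  }
}
tab <- do.call(rbind, rows)
compareNetworkMetrics(tab, metrics = c("mean_wpli", "strength",
                                       "global_efficiency", "char_path_length"))
```

```
   band            metric     t df        p mean_x mean_y
1 alpha         mean_wpli  8.43  7 6.52e-05  0.373  0.304
2 alpha          strength  8.43  7 6.52e-05  4.104  3.343
3 alpha global_efficiency  9.64  7 2.71e-05  0.384  0.311
4 alpha  char_path_length -4.08  7 4.68e-03  3.262  3.551
```

The generator plants stronger alpha coupling under nostalgic stimulation
(g = 0.8 vs 0.3), and the pipeline recovers it: mean WPLI, strength and
global efficiency are higher for nostalgic trials (`mean_x`) than
non-nostalgic (`mean_y`), path length is shorter, all at p < 0.01 with
n = 8 subjects.

The behavioral arm, at the full n = 38:

```r
b <- generateBehavior(simConfig(nSubjects = 38, seed = 42))
rmAnova(cellMeans(b, "pleasure"))
```

```
                 effect df df_error        F gg_epsilon      p_gg   eta2p
1           channelType  2       74   17.256     0.9763 9.178e-07 0.31805
2             musicType  1       37 2552.119     1.0000 9.689e-36 0.98571
3 channelType:musicType  2       74    3.988     0.9181 2.606e-02 0.09731
```

Nostalgic stimuli raise pleasure ratings (the music-type main effect), with
the Greenhouse–Geisser ε, corrected p and partial η² per effect.

`runPipeline(pipelineConfig(...))` executes the whole study — simulation,
preprocessing, spectra, connectivity, networks, statistics — into an output
directory with tidy CSVs and a manifest of checksums; identical config +
seed reproduces identical checksums. A thin CLI
(`inst/scripts/eegpipeline.R`) exposes `simulate` and `run-all`
subcommands; recordings are read and written as BrainVision
(`.vhdr`/`.vmrk`/`.eeg`) triplets.

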