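---
title: "Functional brain networks from EEG: methods and design notes"
author: "wpliNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional brain networks from EEG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wpliNet)
```

# The analysis this package implements

wpliNet analyzes multichannel EEG recorded under a fully within-subject
3 (sensory channel: visual, auditory, audiovisual) x 2 (music type:
nostalgic, non-nostalgic) design, the paradigm used in studies of
music-evoked nostalgia. The question such studies ask is whether an
emotional manipulation changes the *coordination* between cortical areas,
not just the power at single electrodes; the package therefore runs two
parallel arms:

* a **neural arm**: preprocessing, per-band weighted phase lag index (WPLI)
  connectivity matrices, weighted graph metrics on those matrices, and
  subject-level paired comparisons between conditions; and
* a **behavioral arm**: per-trial 9-point Likert ratings (state nostalgia
  plus the pleasure/arousal/dominance affect dimensions), outlier screening,
  paired t tests, and a 3 x 2 repeated-measures ANOVA with
  Greenhouse-Geisser correction and simple-effects decomposition.

Because raw recordings for this kind of study are rarely deposited, the
package ships a first-class synthetic-data generator whose defaults encode
the design above, so every stage of the pipeline is testable end to end
against planted ground truth.

# The connectivity model

For channels $x$ and $y$, let $S_{xy}$ be the cross-spectrum estimated in
Hann-windowed segments. The weighted phase lag index is

$$\mathrm{WPLI}_{xy} =
  \frac{\lvert E[\operatorname{Im} S_{xy}]\rvert}
       {E[\lvert\operatorname{Im} S_{xy}\rvert]},$$

with the expectation taken over segments. Only the imaginary part of the
cross-spectrum enters, so instantaneous (zero-lag) mixing — the signature of
volume conduction, where one cortical source projects into many electrodes —
contributes nothing; consistent nonzero phase lags drive the index toward 1.
The implementation computes the estimator per frequency bin inside a band
and averages bins with equal weight (a power-weighted average is available).
When $E[\lvert\operatorname{Im} S\rvert] = 0$ (exactly zero-lag pairs) the
index is defined as 0 and the pair is counted in the matrix metadata.
Segment pooling crosses epochs within a condition: pooling at the segment
level rather than the epoch level maximizes the number of cross-spectral
samples, which matters because the estimator's small-sample bias shrinks
with the number of segments. The plain estimator is used rather than the
debiased squared variant so that values are interpretable on $[0,1]$.

One spectral engine backs both the PSD and connectivity modules (2 s Hann
segments, 50% overlap by default), so power and coupling are estimated from
the same decomposition. `CrossSpectralSamples` stores per-segment channel
coefficients rather than all pairwise products; the Hermitian symmetry
$S_{xy} = \overline{S_{yx}}$ then holds by construction.

# Graph metrics and their conventions

WPLI matrices are analyzed as full weighted graphs: no thresholding or
binarization, because the downstream metrics (strength, efficiency) are
well-defined on weighted complete graphs and thresholding would add a free
parameter. The conventions, all recorded in each result's metadata:

* **Distance rule**: edge length $= 1/w$ (`"neglog"` available). Under this
  rule a complete uniform graph has $E_{glob} = w$ and $L = 1/w$, so global
  efficiency tracks mean connectivity — the behavior expected of
  unthresholded WPLI networks, where mean WPLI and global efficiency move
  together almost one-for-one.
* **Clustering**: Onnela's geometric-mean triangle form, weights normalized
  by the network-wide maximum (Barrat variant available by option).
* **Unreachable pairs** (possible only with explicit zero weights): excluded
  from the characteristic path length, with their count reported; they
  contribute 0 to efficiency.

The clustering coefficient is computed and reported but kept out of the
headline condition contrast, which uses strength, global efficiency, local
efficiency, and characteristic path length.

# Preprocessing chain

The chain is: band-pass (0.1–50 Hz) → notch (49–51 Hz) → bad-channel
interpolation → epoching with baseline correction → ICA ocular removal →
linked-mastoid re-referencing → ±75 µV amplitude rejection. The applied
order is written to each run's manifest, so it is auditable.

Numerical choices:

* **Filters** are 4th-order Butterworth run forward–backward (zero phase).
  The high-pass and low-pass are applied as separate sections: a single
  band-pass design spanning 0.1–50 Hz is numerically ill-conditioned.
  Because a 0.1 Hz high-pass cannot cancel a constant offset within a
  finite record, the band-pass subtracts the channel mean explicitly first.
* **Interpolation** uses inverse-squared great-circle distance weighting on
  an idealized spherical montage. The montage is generated from the 10-10
  grid geometry (row letter → sagittal angle, electrode number → lateral
  angle); exact manufacturer coordinates are unnecessary because positions
  only drive distance weights and region grouping.
* **ICA** is FastICA (symmetric orthogonalization, tanh contrast) with a
  deterministic initialization. The removal criterion — not the
  decomposition algorithm — is the contract: any component whose absolute
  correlation with an EOG channel reaches 0.8 is zeroed before
  back-projection, and removing zero components returns the input bit for
  bit. ICA runs after epoching by default (both entry points are supported);
  decomposing continuous data is the more common practice, but the epoch
  entry point keeps the chain faithful to the design the package models.
* **Amplitude rejection** reads "exceeding ±75 µV" as a strict inequality on
  the absolute peak per epoch, evaluated after baseline correction, on scalp
  channels only.
* **Mastoids** default to TP9/TP10 with M1/M2 accepted as synonyms.
* **Epochs** default to the full 30 s stimulus with the 5 s pre-stimulus
  fixation as baseline. Published descriptions of this paradigm are
  internally inconsistent about epoch length (30 s stimuli vs "~45 s"
  epochs), so the length is an explicit parameter rather than a guess.

# Spectral summaries

Band power integrates the Welch PSD over each band by the trapezoid rule on
closed intervals, so the five canonical bands (δ 1–4, θ 4–8, α 8–13,
β 13–30, γ 30–50 Hz) tile the 1–50 Hz axis exactly and Parseval holds:
summed band power matches in-band signal variance within the estimator's
small-sample bias (about 1% at 30 s). Point queries about which band *owns*
a frequency use the half-open convention [lo, hi): 13 Hz is beta. Relative
power divides by the sum over the five bands — the same 1–50 Hz support as
the analysis band-pass — not by total Nyquist power; a zero denominator
yields flagged `NA`s, never silent NaN propagation. A second band table
(α 8–14, β 14–31, γ 31–50) ships as `resultsSectionBands()` because both
edge conventions circulate; results always record which table produced them.

# The synthetic-data generator

`simConfig()` defaults encode the study conditions: 38 subjects (36 with
usable EEG is the analyzed size in this literature), 64-channel extended
10-20 montage at 500 Hz, 30 s trials, 5 trials per design cell presented in
visual → auditory → audiovisual block order with randomized music types
within blocks.

**Coupling mechanism.** Each band's common source is synthesized directly in
the frequency domain — i.i.d. complex Gaussian coefficients on the band's
bins, zero elsewhere — yielding an exactly band-limited analytic signal.
(An earlier filter-based source was replaced: a Butterworth's transition
skirts let condition-dependent gamma coupling leak into beta and mimic a
false beta effect.) Each coupled channel receives the source rotated by a
per-subject phase offset with magnitude uniform in (π/4, π/2) and
alternating sign across channels, so phase-lag signs are consistent over
time and the planted WPLI is controllably high. Offsets are fixed per
subject, not per trial, keeping condition contrasts within-subject. Mixing
strength is `g(band, musicType)`; defaults plant elevated alpha and gamma
coupling under nostalgic stimulation (0.8 vs 0.3) and equal null coupling
(0.4) in theta and beta.

**What is emulated**: 1/f (pink) background noise so relative-power code is
exercised nontrivially; stereotyped ~0.4 s blinks spread over anterior
channels by montage distance and written strongly to simulated VEOG/HEOG
(so ICA removal is testable against the known blink time course); 50 Hz
line noise; occasional high-amplitude movement spikes whose trial indices
are recorded as ground truth for rejection tests; Likert ratings drawn as
cell mean + Gaussian noise, truncated and rounded to the 1–9 grid, with
cell means and SDs calibrated to published descriptive statistics for this
paradigm.

**What is not emulated** — and hence what passing tests do and do not show:
there is no head model or volume conduction (coupling is planted directly,
so tests certify estimator and pipeline correctness, not robustness to
realistic source mixing beyond the common-source checks); no non-stationarity
within trials; no muscle or cardiac artifacts; ratings have no
between-subject random effects (each cell's draws share one mean), which
makes simulated F statistics larger than those of real subjects at the same
cell means.

A note on reproducibility engineering: per-subject random streams are
derived from the master seed through a mixing function whose final
multiplicative step spreads consecutive subject indices far apart.
Mersenne-Twister streams started from adjacent integer seeds are weakly
correlated, and that correlation was measurable as an inflated type-I error
of across-subject t tests before the fix.

# Statistics

* Outlier screening is a single, non-iterative pass: values beyond
  $k = 3$ SD of the full-sample mean are dropped. It operates on
  subject-level condition means, the unit of every reported test.
* The repeated-measures ANOVA partitions sums of squares subject-wise with
  each effect tested against its own subject x effect error stratum.
  Greenhouse-Geisser ε is computed from the covariance of the effect's
  orthonormal contrast scores, ε = (Σλ)² / (d·Σλ²); for 1-df effects ε = 1
  identically. Partial eta-squared is SS_effect / (SS_effect + SS_error).
  The implementation agrees with `car::Anova(type = 3)` univariate output to
  1e-9 (checked in the test suite), and with F = t² on 2-level factors.
* Simple effects are pairwise paired t tests at fixed levels of the other
  factor, reported uncorrected by default (the common practice in this
  literature) with Holm/FDR available and the choice flagged in the output.
* Band-wise network comparisons default to uncorrected per-band p values
  with a multiplicity note attached; FDR is one option away. Whole-matrix
  condition contrasts are reported at both the subject level and the
  matrix-entry level, labeled by sampling unit, because entry-level t
  statistics (computed across the thousands of matrix cells) are orders of
  magnitude larger and the two must never be conflated.

# Problem sizes used by the tests and acceptance script

Simulation-backed checks run at deliberately reduced scale, chosen as the
smallest sizes at which each effect is cleanly measurable: 6–16 channels,
128 Hz sampling, 4–8 s trials, 1–2 trials per cell, 8–36 subjects. The
directional-recovery experiment uses 36 subjects (the analyzed sample size
of the design being modeled) with 10 channels at 128 Hz; null calibration
uses 200 replicate 8-subject studies. Behavioral checks run at the full
n = 38 across 100 seeds, since ratings are cheap to draw. The defaults of
`simConfig()` remain the full-scale study conditions.

# Known limitations

* The EEG reader/writer supports BrainVision (multiplexed binary,
  IEEE_FLOAT_32 or INT_16); EDF+ input is not implemented.
* Spherical-spline interpolation is not implemented; inverse-distance
  weighting is used, which is adequate for the isolated-bad-channel case the
  pipeline handles (bad channels are supplied by configuration, not
  detected).
* No source-space analysis, time-frequency decompositions, or alternative
  connectivity estimators (PLI, coherence, Granger) — the scope is the
  WPLI network pipeline and its statistics.
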