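---
title: "Quantifying puromycin-induced release of translation-site puncta"
author: "punctaKinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying puromycin-induced release of translation-site puncta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(punctaKinetics)
```

## The measurement

SunTag-type translation reporters render actively translating polysomes
as diffraction-limited fluorescent puncta: an epitope array on the
nascent chain is bound co-translationally by a GFP-fused single-chain
antibody, so each translation site appears as a bright spot over a
diffuse cytoplasmic pool of free antibody. When puromycin — an
aminoacyl-tRNA analogue that is covalently joined to the nascent chain
and terminates elongation — is added during live imaging, puncta
disappear as puromycylated nascent chains are released from ribosomes
and the reporter signal returns to the diffuse pool. The rate at which
puncta vanish after drug addition is therefore a direct, live-cell
readout of the release kinetics of puromycylated nascent chains, and
how elongation-inhibitor pretreatment (emetine, cycloheximide) changes
those kinetics discriminates between mechanistic models of whether
inhibitors can trap puromycylated chains on ribosomes.

This package implements that measurement as a reusable, fully testable
pipeline: a synthetic-movie generator with the statistical structure of
such trials, from-scratch Laplacian-of-Gaussian (LoG) spot detection,
per-cell trajectory construction with a photobleaching quality-control
rule, decay-time extraction on smoothed normalised trajectories, and
the two hypothesis tests used to compare conditions. A parallel
still-image mode covers per-cell quantification of immunofluorescence
(IF) and proximity-ligation (PLA) images.

## The analysis chain

For each imaging trial (one field, 7-12 cells, ~8 min with drug added
at 60 s and irregular ~5.4-s frame intervals), the analysis is:

1. **Spot detection** (`detectSpots`). The scale-normalised LoG
   response $-\sigma^2 \nabla^2 (G_\sigma * I)$ is computed at the
   scale implied by an estimated blob diameter $d$ via
   $\sigma = (d/2)/\sqrt{2}$ — the standard 2-D relation between a
   blob's radius and the LoG scale that maximises its response.
   Defaults are $d = 0.5\ \mu m$ and a quality (peak response)
   threshold of 300 on the 16-bit-like intensity scale. Local maxima
   closer than one blob diameter are reduced to the highest-quality
   one; optional minima on contrast (disc-vs-annulus) and total disc
   intensity, plus a nucleus exclusion mask, suppress unwanted
   detections.
2. **Per-cell series** (`buildCellSeries`). Spots are assigned to
   manually provided cell masks by centre-pixel membership; per frame,
   each cell gets a puncta count and the mean reporter intensity over
   its cytoplasm (cell mask minus nucleus mask when available — the
   region is not prescribed by the protocol, so the package picks the
   region the reporter actually occupies).
3. **Quality control** (`qcPhotobleach`). The cytoplasmic trace is
   normalised to the mean of its first 10 frames; cells whose trace
   falls more than 10% below baseline (photobleaching, focus loss) are
   discarded. The trace is first smoothed with a centred rolling mean
   of window 10 so that a single-frame focus glitch does not discard a
   cell; the unsmoothed alternative ("any frame below 0.9") would be
   dominated by single-frame noise, and an endpoint-only rule would
   miss mid-trial focus loss. The smoothed-minimum rule is this
   package's declared reading of the 10% criterion.
4. **Normalisation and smoothing** (`normalizeCounts`). Each cell's
   counts are divided by its mean count over frames strictly before
   60 s (pre-drug). A frame stamped exactly at the drug time is
   treated as post-drug. The replicate-mean trajectory is smoothed
   with a boxcar (rolling mean) of $k = 10$ observations; windows are
   centred and truncated at the edges so trajectory length is
   preserved.
5. **Decay times** (`decayTime`, `summarizeReplicate`). For fractions
   2/3, 1/2 and 1/3, all post-drug frames whose smoothed value lies
   within $\pm 0.01$ of the fraction are averaged (their mean
   timestamp, minus the drug time, is $t_{2/3}$, $t_{1/2}$,
   $t_{1/3}$). Restricting the band to $t \ge t_{drug}$ keeps pre-drug
   noise near a fraction from contaminating the average; all band
   frames are used, contiguous or not. When a steep decay skips the
   band entirely between two frames, the package falls back to linear
   interpolation of the crossing and flags the estimate as
   `interpolated`. A trajectory that never reaches the fraction (the
   vehicle control) is reported as `not_reached` rather than an error.
   Replicate summaries are computed on the replicate-mean trajectory;
   cells are aligned onto the union of their timestamps by
   nearest-frame lookup, since fields are in general imaged
   asynchronously.
6. **Summary curves and tests** (`binCurve`, `welchT`,
   `mannWhitney`). Normalised counts are pooled into half-open 5-s
   bins (mean, sample sd, n; sd reported as 0 for singleton bins, bin
   edges assigned rightward). Replicate decay times are compared with
   Welch's t-test; still-image intensity distributions with the
   Mann-Whitney U test.

```{r example, eval = FALSE}
emt <- runReleaseExperiment(ReleaseKinetics("exponential", kRel = 0.021),
                            seed = 1)
veh <- runReleaseExperiment(ReleaseKinetics("vehicle"), seed = 1)
meanDecayTime(emt$summaries, 0.5)
compareDecayTimes(emt$summaries, veh$summaries)
```

## What the generator emulates

`simulateMovie` renders trials with the structure the analysis assumes,
so every downstream stage is testable against ground truth without any
external data:

- **Acquisition clock**: intervals drawn from a truncated normal with
  mean 5.4 s, sd 1.9 s, clipped by re-drawing to [2.5, 9.8] s (only
  these summary statistics of the real acquisition are known); trials
  last 480 s with drug at 60 s.
- **Field geometry**: 8 elliptical cells on a jittered grid in a
  256x256 field at 0.16 um/px (16-um camera pixels at 100x; the
  hardware implies the order of magnitude, and the value is
  configurable). Each cell holds a punctum-free elliptical nucleus,
  rendered dimmer than the cytoplasm, so nuclear-suppression filtering
  is exercisable.
- **Puncta**: 30 per cell, Gaussian PSF of sd 0.17 um, placed
  uniformly in the cytoplasm with a minimum pairwise separation of
  0.64 um. The separation floor reflects that the counting analysis
  presumes countable, individually resolvable puncta; without it a
  fixed fraction of puncta overlap within one blob diameter and are
  merged by any single-scale detector.
- **Release kinetics** (`ReleaseKinetics`): per-punctum disappearance
  — the whole punctum vanishes at its release time. This is the
  minimal model reproducing count decay, since the readout is counts,
  not intensities; an optional multi-chain mode
  (`chainsPerPunctum > 1`) instead fades puncta in proportion to
  surviving chains and removes them below a detectability fraction.
  Four regimes: `vehicle` (no disappearance), `instant` (limit case),
  `exponential` (rate $k_{rel}$ after drug; the no-lag, emetine-like
  regime) and `two_stage` (Exp($k_{bind}$) binding delay then
  Exp($k_{rel}$) release; the cycloheximide-like regime — slowed
  disappearance attributed to hindered puromycin binding at a crowded
  A site, not to slower release).
- **Photophysics and noise**: all signal decays as
  $e^{-\lambda_{bleach} t}$ with $\lambda_{bleach} = 10^{-4}/s$
  (~4.7% over a trial, inside the <10% loss a control cell must keep
  to pass QC); Poisson shot noise (gain 1) then Gaussian read noise
  (sd 3) on a 16-bit-like scale with background 200, cytoplasm +300
  and punctum amplitude 2000. With the default PSF this amplitude
  yields a LoG peak quality of ~1000, which is what makes the
  detector's default threshold of 300 meaningful on synthetic data.
  The absolute calibration of the original software's quality scale on
  the real camera is unrecoverable, so the procedure — not that
  constant — is what the detector reproduces.
- **Fluorescence conservation**: the integrated intensity of a
  released punctum is returned to its cell's diffuse cytoplasmic pool.
  This mirrors the reporter's physics (the antibody is not degraded,
  it unbinds and diffuses) and is what keeps cytoplasmic intensity —
  and hence the QC — flat in cells that lose all their puncta.

`simulateStillExperiment` renders the still-image analogue: per
condition, cells with Poisson-distributed puncta counts around the
condition mean and a condition-level diffuse intensity. Defaults encode
a strongly labelled positive condition (mean 200 puncta/cell) and an
antibody-omission control (mean 4, i.e. below 8); dense PLA-like puncta
are allowed to sit closer together (0.32 um) than movie puncta, as real
amplification puncta do.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: cell-to-cell variability in expression and
shape beyond ellipse jitter, spatial heterogeneity of background,
stage drift and focus excursions (QC failures are simulated only via
bleaching), punctum movement between frames, 3-D structure collapsed
into 2-D, and mRNA-channel signal. Detection performance on synthetic
frames (recall and precision above 0.95 in tests) is an upper bound on
real-data performance, not an estimate of it.

## Numerical choices

- **LoG implementation**: the kernel is sampled analytically out to
  $4\sigma$ and made zero-sum, so constant images give exactly zero
  response; convolution uses reflective (half-sample symmetric)
  padding, and maxima within $\lceil \sigma \rceil$ of the border are
  discarded. Tests verify the response against a brute-force direct
  convolution oracle at relative tolerance $10^{-6}$ away from
  borders.
- **Sub-pixel localisation is not performed**: the analysis readout is
  counts per cell, and integer-pixel maxima are sufficient for
  membership decisions. Equal-quality neighbouring maxima are resolved
  toward the smaller (row, col) index, making detection deterministic.
- **Decay-time bias**: boxcar smoothing biases threshold crossings of
  an exponential; over a symmetric window of half-width $w$ the
  smoothed curve is the true curve times $\sinh(\lambda w)/(\lambda w)$,
  which shifts the half-crossing to
  $(\ln 2 + \ln[\sinh(\lambda w)/(\lambda w)])/\lambda$. Tests hold
  the extractor to within 10% of this closed form on a noiseless
  sampled exponential ($\lambda = 0.02$/s, 5-s spacing, $k = 10$).
- **Statistics**: Welch's t reports real-valued Welch-Satterthwaite
  degrees of freedom. (Published decay-time comparisons of this design
  print integer pooled-style df; the package deliberately reports the
  Welch df rather than matching an integer print format.) The
  Mann-Whitney U test is exact — full null distribution by the
  counting recursion, two-sided p as twice the smaller tail, capped at
  1 — whenever both samples are at most 20 and no tied value spans the
  groups; otherwise it uses the tie-corrected normal approximation
  with continuity correction. Exactness is verified against complete
  enumeration of all group assignments for $n_1 + n_2 \le 10$.
- **Degenerate inputs**: zero baseline counts exclude a cell with a
  logged reason rather than propagating NaN; fewer than 10 frames is
  an error for QC (no baseline); both-samples-constant with equal
  means is an error for Welch's t (0/0); a trajectory that never
  reaches a fraction is a distinguished `not_reached` result.

## Problem sizes and reproducibility

End-to-end checks and the acceptance script use the study's design
point — 3 replicates of 8 cells x 30 puncta per condition on 256x256
frames — which the full pipeline processes in tens of seconds per
condition; unit tests use 2-cell, 96x96 configurations. All randomness
descends from a single integer seed (per-replicate seeds are derived
deterministically), and fixed-seed outputs are bit-identical, which
the tests assert for the generator, the pipeline and the command-line
interface.

## Known limitations

- Single-scale detection: puncta are assumed mono-disperse at the
  configured blob diameter; no multi-scale or sub-pixel refinement.
- No frame-to-frame linking: the statistic is per-frame counts, so
  nothing constrains a punctum's identity across frames, and
  blinking/refocusing artefacts enter as count noise.
- Cell segmentation is an input (masks), matching the manual
  segmentation of the original workflow; no automated segmentation is
  provided.
- The decay-time band rule averages timestamps, so it is well defined
  only for roughly monotone trajectories; vehicle-like flat
  trajectories report `not_reached` by design.
- Model-based curve fitting (exponential/hypoexponential regression)
  is intentionally out of scope; the threshold-crossing statistic is
  nonparametric and matches the published procedure.
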