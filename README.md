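# punctaKinetics

Quantifies how fast translation-site puncta disappear after puromycin
addition in live-cell time-lapse microscopy, and provides the
synthetic data needed to test every stage of that analysis.

SunTag-type reporters make translating polysomes visible as
diffraction-limited puncta: a GFP-fused single-chain antibody binds an
epitope array on the nascent chain. Puromycin terminates elongation by
covalent incorporation into the nascent chain; whether (and how fast)
the puromycylated chain then leaves the ribosome — especially under
elongation-inhibitor pretreatment with emetine or cycloheximide — is
read out directly as the decay of the per-cell puncta count. This
matters for interpreting puromycin-based in-situ translation assays
(ribopuromycylation, puromycin-proximity-ligation), which assume the
labelled chain stays put.

The package is aimed at microscopy groups doing live-cell translation
imaging or IF/PLA quantification who want the published analysis chain
as tested, scriptable functions rather than an ImageJ click-path.

## The analysis

For each trial (one field of cells, drug added at `t_drug = 60` s,
irregular ~5.4-s frames over ~8 min):

1. **LoG spot detection.** Scale-normalised Laplacian-of-Gaussian
   response `-sigma^2 * Laplacian(G_sigma * I)` with
   `sigma = (d/2)/sqrt(2)` for estimated blob diameter `d = 0.5` um;
   local maxima thresholded on peak response ("quality", default 300),
   de-duplicated within one blob diameter, with per-spot contrast and
   total-intensity features and optional nucleus exclusion.
2. **Per-cell series.** Counts by centre-pixel membership in cell
   masks; mean cytoplasmic reporter intensity per frame.
3. **QC.** Cells whose cytoplasmic intensity (normalised to the mean
   of the first 10 frames, smoothed with a width-10 rolling mean)
   drops more than 10% below baseline are discarded.
4. **Kinetics.** Counts are normalised per cell to the mean over
   `t < 60` s, the replicate-mean trajectory is boxcar-smoothed
   (k = 10), and the decay times `t_2/3`, `t_1/2`, `t_1/3` are the
   mean timestamps of all post-drug frames within ±0.01 of each
   fraction (linear interpolation when a steep decay skips the band;
   `not_reached` for flat controls). 5-s bins give mean ± sd summary
   curves.
5. **Statistics.** Welch's t-test (real-valued Welch–Satterthwaite df)
   for decay-time comparisons; exact small-sample Mann–Whitney U for
   still-image intensity distributions.

The synthetic generator (`simulateMovie`, `simulateStillExperiment`)
renders movies with per-punctum release kinetics — `vehicle`,
`instant`, `exponential` (rate `k_rel`, no lag) or `two_stage`
(binding delay then release, producing a lag shoulder) — plus Gaussian
PSF, photobleaching, Poisson + Gaussian camera noise and ground-truth
tables for recovery testing.

## Worked example

Three simulated replicates of an emetine-like condition (no binding
lag, per-punctum release at 0.021/s) against a cycloheximide-like
condition (mean 215-s binding delay, fast release), analysed end to
end:

```r
library(punctaKinetics)
emt <- runReleaseExperiment(ReleaseKinetics("exponential", kRel = 0.021),
                            seed = 1)
emt$summaries
#>   replicate   condition fraction  time nBand       method
#> 1        r1 exponential   0.6667 20.25     0 interpolated
#> 2        r1 exponential   0.5000 35.59     1 band_average
#> 3        r1 exponential   0.3333 50.18     1 band_average
#> 4        r2 exponential   0.6667 20.62     0 interpolated
#> ...
meanDecayTime(emt$summaries, 0.5)
#> [1] 34.83794

chx <- runReleaseExperiment(
  ReleaseKinetics("two_stage", kBind = 1/215, kRel = 0.2), seed = 2)
compareDecayTimes(chx$summaries, emt$summaries)
#>   fraction  meanA meanB nA nB      t    df        p nNotReached
#> 1   0.6667  91.27 20.75  3  3 15.445 2.021 0.003985           0
#> 2   0.5000 159.77 34.84  3  3  9.393 2.019 0.010806           0
#> 3   0.3333 252.29 52.69  3  3 11.905 2.125 0.005560           0
```

`time` is seconds after drug addition: the no-lag condition loses half
its puncta in ~35 s, the slow-binding condition in ~160 s (about 2 min
later), and the Welch tests resolve the difference at every fraction.
`method` records whether each estimate came from the ±0.01 band rule
or from interpolation across a steep crossing.

A thin CLI over the same functions lives at
`inst/scripts/puncta-pipeline.R`
(`simulate-movie`, `simulate-stills`, `detect`, `quantify`,
`kinetics`, `compare`, `run-all`), reading/writing multi-page TIFF
movies with JSON timestamp sidecars, label-image masks and
TrackMate-compatible spot CSVs.

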