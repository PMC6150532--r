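# usvdyad

Who emitted that call? `usvdyad` analyzes ultrasonic vocalizations (USVs)
recorded from freely interacting male–female mouse pairs with an 8-channel
microphone array, assigning each call to an individual mouse and testing
whether, and in which behavioral contexts, male and female vocalizations
differ. It is written for bioacousticians and behavioral neuroscientists
working with microphone-array recordings of rodent social behavior.

## What it does

* **Detects** vocal signals as connected time–frequency regions: multitaper
  spectrograms (K = 5 Slepian tapers, NW = 3; window lengths 64/128/256
  samples at 250 kHz) with Thomson's harmonic F-test (p < 0.05, F(2, 2K−2))
  per bin, masks OR-ed across all channels and scales, gap-filled with an
  11 × 15 box kernel, components of ≥ 1500 pixels kept, harmonic stacks
  collapsed to their fundamental.
* **Localizes and assigns**: leave-one-microphone-out jackknifing of a
  GCC-PHAT + least-squares source estimator gives 8 estimates per call;
  their mean and (floored) jackknife covariance define a density D over the
  cage, and the mouse probability index
  `MPI_n = D_n / Σ_i D_i`, evaluated at each animal's nose, assigns the
  call when `max MPI > 0.95`.
* **Quantifies** seven per-call features: bandwidth, duration, high/low
  frequency, mean fundamental frequency, slope (robust bisquare regression
  of the frequency contour), and sine-fit amplitude.
* **Classifies context** from 30 fps trajectories: *following* / *followed*
  (directions within 25°, distance < 5 cm, both speeds > 20 cm/s, pursuer
  behind leader, ≥ 10 consecutive frames) and *not close* (≥ 15 cm,
  ≥ 10 frames).
* **Compares the sexes**: Mann–Whitney U tests (exact for small n,
  tie-corrected normal otherwise), Pearson correlations, per-animal
  medians, a high/low-vocalizer split at 2200 calls, and a Monte-Carlo
  index — 1000 subsamples of 500 calls per sex, index
  `(male median − female median) / (male median + female median)`, with
  slopes shifted by |most negative slope| so the formula applies to the one
  signed feature.
* **Simulates** everything with ground truth: scripted social bouts,
  linear-FM chirps, free-field 8-channel array audio, and S1-style
  per-vocalization feature tables whose per-sex distributions match the
  published pooled medians and IQRs.

## Worked example

Simulate a dyad session with 12 planted chirps, run the whole pipeline,
and summarize:

```r
library(usvdyad)

rep <- run_pipeline(stages = c("simulate", "segment", "localize",
                               "features", "behavior", "stats"),
                    seed = 42, out_dir = "demo_run",
                    n_events = 12, n_samples = 100, sample_size = 5)
str(rep$stages[c("segment", "localize")])
#> List of 2
#>  $ segment :List of 1
#>   ..$ n_signals: int 12
#>  $ localize:List of 2
#>   ..$ n_signals : int 12
#>   ..$ n_assigned: int 12

feats <- read_feature_table("demo_run/features_labelled.csv")
feats[1:3, c("emitter", "bandwidth_hz", "duration_ms", "slope_hz_per_s", "context")]
#> <feature_table: 3 vocalizations (3 assigned)>
#>   emitter bandwidth_hz duration_ms slope_hz_per_s   context
#> 1       M     15909.06      22.144       733718.7 not_close
#> 2       F     13646.34      28.672       484239.3 not_close
#> 3       M     21673.94      15.872      1411277.7 not_close
```

All 12 planted chirps were detected, localized and assigned to the correct
emitter (`n_assigned = 12`); each row carries the seven acoustic features
and the emitter's behavioral context at call onset. On the statistical
side, the default synthetic feature table reproduces the structure the
package is built to test:

```r
tab <- simulate_feature_table(seed = 1)
summarize_feature_table(tab, seed = 2)
#> USV summary: 67863 signals, 67863 assigned (86.5% male)
#>   pooled bandwidth: male 7.87 kHz vs female 6.08 kHz (p = 1.01e-285)
#>   index bandwidth_hz    1000 male-driven /    0 female-driven
#>   index duration_ms      129 male-driven /  871 female-driven
#>   index high_freq_hz     971 male-driven /   29 female-driven
#>   index low_freq_hz      260 male-driven /  740 female-driven
#>   index mean_freq_hz     797 male-driven /  203 female-driven
#>   index slope_hz_per_s     0 male-driven / 1000 female-driven
#>   index amplitude_mv     959 male-driven /   41 female-driven
```

Males dominate call counts (~86% of assigned calls), male bandwidth
exceeds female bandwidth in every one of the 1000 Monte-Carlo subsamples,
and every slope index is female-driven (female calls rise in pitch more) —
the two directions that survive sample-size and individual-variability
controls.

A thin command-line front end wraps the same pipeline:

```sh
Rscript inst/scripts/usvdyad --stages simulate,segment,localize,features,behavior,stats \
        --seed 42 --out-dir demo_run
```

## Package layout

| Piece | Contents |
|---|---|
| `R/wav.R`, `R/session.R`, `R/feature_table.R`, `R/tracks.R` | WAV/YAML/CSV readers and writers, session bundles |
| `R/synth_*.R` | trajectory, chirp, array-audio and feature-table simulators |
| `R/dpss.R`, `R/multitaper.R`, `R/segment.R` | Slepian tapers, F-test spectrograms, mask fusion, signal extraction |
| `R/localize.R` | GCC-PHAT, jackknife localization, MPI assignment |
| `R/features.R` | contour features, robust slope, sine-fit amplitude |
| `R/behavior.R` | kinematics, pursuit/not-close classification, context labels |
| `R/stats.R`, `R/analysis.R` | Mann–Whitney, Monte-Carlo index, table summaries |
| `R/pipeline.R` | stage runner and session simulator |
| `vignettes/usv-dyad-methods.Rmd` | the methods vignette (models, parameters, limitations) |

See the methods vignette for the full model description, every tunable
parameter with units and defaults, and what validation on synthetic data
does and does not establish.
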