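# squeaktrace

Attribution of mouse ultrasonic vocalizations to individual animals in
freely interacting dyads, and statistics for the receiver's behavioral
response.

## Why

Adult mice emit ultrasonic vocalizations (USVs, 30–110 kHz) almost
exclusively during close social interaction, and nothing visible marks
which animal is calling. Researchers recording a pair of mice with an
eight-microphone array and overhead video therefore need a computational
chain to answer two questions: *who vocalized*, and *did the other mouse
respond*. `squeaktrace` implements that chain end to end, plus a
synthetic-data generator with complete ground truth (tracks, emissions,
vocalizer identities, eight-channel audio) so every stage is testable
without any recordings.

## What it computes

1. **Segmentation** — each channel is band-passed (30–110 kHz) and scanned
   with the multitaper harmonic F-test (K = 5 Slepian tapers, NW = 3,
   window lengths 64/128/256 samples, per-pixel alpha = 0.05, reference
   distribution F(2, 2K−2)). Masks are combined across channels by a 5-of-8
   vote, merged across window lengths on the finest common raster, dilated
   with an 11 × 15 pixel box, and 8-connected components with ≥ 1500 pixels
   become vocal signals with start/stop times and frequency contours
   (harmonics folded into their fundamental).
2. **Localization** — pairwise arrival-time differences by
   cross-correlation; eight leave-one-microphone-out (jackknife) source
   estimates by hyperbolic least squares; a bivariate Gaussian source
   density over the arena from the eight points; and the **Mouse
   Probability Index** for each animal n of M,

   MPI_n = D_n / Σ_{i=1..M} D_i,

   where D_n is the density at mouse n's nose. A signal is attributed only
   when max MPI ≥ 0.95.
3. **Social dynamics** — per-frame inter-mouse distance, time in close
   proximity (< 20 cm, overall and per minute), time to a given fraction of
   emissions, per-mouse median/IQR emission distance, and a group-comparison
   helper implementing the small-sample nonparametric policy (n < 15 →
   Mann-Whitney / Kruskal-Wallis + Dunn).
4. **Response statistics** — 11-frame (367 ms) receiver-speed trajectories
   around emissions; greedy speed-matching of each to an unused non-vocal
   window over the first 200 ms; post-emission acceleration (mean of the 5
   frame-to-frame speed changes in the 167 ms after emission); paired
   t-tests per (vocalizer × relative-speed) stratum; subsampling null
   distributions (25% or size-matched draws, 1000 reps); and an epoch
   analysis over three 10-minute bins with epoch-restricted controls.

## Worked example

```r
library(squeaktrace)
cfg <- default_run_config(master_seed = 3, duration_s = 120)
out <- run_pipeline(cfg)
out$report$n_events_truth        # 69   emissions generated
out$report$n_assigned            # 58   signals with max MPI >= 0.95
out$report$attribution_accuracy  # 1    all assigned signals correct
round(out$report$proximity_fraction, 3)  # 0.984 of frames within 20 cm
out$response$table
#>   vocalizer relative_speed  n vocal_mean control_mean      t     p
#> 1         1         faster  5     0.1777       0.4064 -1.440 0.223
#> 2         2         faster  9    -0.1950       0.0414 -1.539 0.162
#> 3         1         slower 10     0.0407      -0.1120  0.967 0.359
#> 4         2         slower 11     0.0686      -0.1978  1.697 0.121
```

With no injected response (`kick_magnitude = 0`) no stratum is
significant, as it should be; `inject_response_kick()` adds a known
post-emission acceleration to the receiver and the same table recovers it.
The audio path (`localization = "array"`) renders 250 kHz eight-channel
audio, segments it, and localizes each detected signal; use short
durations, as 1 s of audio is 2 M samples.

A thin CLI wraps the same pipeline:

```sh
Rscript inst/cli/squeaktrace all --config run.yaml --out results/
```

## Documentation

The methods vignette (`vignettes/methods.Rmd`) describes the models, the
parameters and their defaults, the numerical choices, and what synthetic
validation does and does not establish about real recordings.
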