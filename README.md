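# odplast

Measurement pipelines for ocular dominance (OD) plasticity experiments in
mouse primary visual cortex. The package implements, as tested reusable
code, the three quantitative readouts such experiments rest on:

1. **Intrinsic-signal imaging → ocular dominance index (ODI).**
   Widefield reflectance movies acquired during continuous periodic bar-sweep
   stimulation are reduced to per-pixel response-magnitude maps by Fourier
   analysis at the stimulus frequency: for a pixel time series with DFT `X`,
   the response is `2|X(f_stim)| / X(0) × 10⁴` (fractional reflectance change
   × 10⁴). Per eye, the two drift-direction maps (90°/270°) are averaged and
   smoothed with a 5 × 5 Gaussian; the binocular ROI is thresholded at 30% of
   the peak of the smoothed ipsilateral map; and the ODI is the ROI average of
   the pixelwise index `(C − I) / (C + I)`, where `C` and `I` are the
   contralateral- and ipsilateral-eye magnitudes.

2. **Sr²⁺-desynchronized quantal EPSC analysis.** In Sr²⁺, evoked release
   desynchronizes into quantal events whose amplitudes report unitary
   postsynaptic strength. Events are detected at 3 × RMS noise with a 3 ms
   rise-time inclusion limit (cells with RMS > 2 pA excluded); spontaneous
   events are quantified in a 400 ms pre-stimulation window and evoked
   activity in a 400 ms window starting 50 ms after stimulation; the evoked
   quantal amplitude is corrected for the spontaneous contribution by

   ```
   (postAmp × postFreq − preAmp × preFreq) / (postFreq − preFreq)
   ```

3. **STDP quantification from current-clamp EPSPs.** Synaptic strength is
   the initial slope (first 2 ms) of the EPSP; the baseline is the mean of 30
   consecutive pre-drug sweeps; plasticity magnitude is the late
   post-induction slope (default 25–30 min window) as a percent of baseline.

Because raw data of this kind are rarely deposited, the package includes
first-class, seeded synthetic-data generators for all three modalities
(`imaging_truth()`/`gen_session()`, `ephys_truth()`/`gen_sr_sweeps()`,
`gen_stdp_sweeps()`) whose ground truth makes every downstream stage testable
— parameter recovery, not just smoke tests. The same analysis entry points
accept real data through a CSV + JSON-sidecar schema (`read_intrinsic_stack()`,
`read_sweep_set()`).

## Worked example

```r
library(odplast)

# --- imaging: one synthetic session at true ODI 0.30 ---------------------
truth   <- imaging_truth(64, 64, odi = 0.30, noise_sd = 1e-3, seed = 42)
session <- gen_session(truth, duration = 300, frame_rate = 30, stim_freq = 0.12)
analyze_session(session)
#> <odi_result> ODI 0.2888  (C 2.217, I 1.214 x1e4; 875 ROI px)

# --- quantal EPSCs: 12 pA spontaneous @ 1 Hz, 18 pA evoked ----------------
cell <- gen_sr_sweeps(ephys_truth(noise_rms = 1.5, seed = 42), n_sweeps = 60)
analyze_cell(cell$sweeps)
#> <quantal_estimate> evoked 19.24 pA (pre 11.71 pA @ 1.21 /s; post 17.97 pA @ 7.17 /s; rms 1.50 pA)

# --- STDP: slope ratio 1.235 after pairing --------------------------------
stdp <- gen_stdp_sweeps(post_ratio = 1.235, seed = 42)
analyze_stdp(stdp$sweeps)
#> <plasticity_result> 123.6% of baseline (baseline 1.968 mV/ms, endpoint 25-30 min, n=16)
```

The imaging run recovers the true ODI of 0.30 to within the expected noise
(±0.02 across seeds); the quantal estimate recovers the 18 pA evoked
amplitude after removing the spontaneous-event contribution; the STDP run
recovers the induced 123.5% potentiation to within the per-sweep slope
jitter.

An end-to-end simulated study (before/after imaging comparison across
animals, a population of quantal cells, and an STDP series per condition)
runs from one seeded config:

```r
run_pipeline(system.file("extdata", "demo_config.json", package = "odplast"),
             out_dir = "demo_report", seed = 1)
```

writing `imaging_sessions.csv`, `imaging_group.json`, `quantal_cells.csv`,
`quantal_summary.json`, `stdp_slopes.csv`, `stdp_summary.csv` and a full
parameter log. Reruns with the same config and seed are byte-identical. The
same pipeline is exposed on the command line via
`Rscript inst/cli/odmap.R report --config cfg.json --out DIR --seed N`
(subcommands: `report`, `map`, `odi`, `quantal`, `stdp`).

## Documentation

Every exported function carries roxygen documentation; the methods vignette
(`vignettes/odplast-methods.Rmd`) describes the models, the synthetic world
and its defaults, numerical choices, and known limitations.
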