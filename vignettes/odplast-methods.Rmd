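---
title: "odplast: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{odplast: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the measurement models implemented in `odplast`, the
synthetic world the generators emulate, and the numerical and design choices
made where the underlying experimental conventions leave room. It states no
empirical result that the test suite does not itself compute.

# Intrinsic-signal imaging and the ocular dominance index

## Signal model

Continuous periodic-stimulus intrinsic imaging drives cortex with a bar
sweeping at a fixed temporal frequency (here `stim_freq`, default 0.12 Hz)
while a camera records reflectance at `frame_rate` (default 30 Hz). A
responsive pixel's reflectance is modeled as

$$R(t) = R_0\,[1 + a(x,y)\cos(2\pi f_{stim} t + \varphi)] + \varepsilon(t),$$

with fractional modulation amplitude $a \sim 10^{-4}$, a hemodynamic phase
$\varphi$ shared within an acquisition, and additive noise $\varepsilon$. The
response map is extracted per pixel from the DFT $X$ of its time series as

$$\text{magnitude} = \frac{2\,|X(k^\*)|}{X(0)} \times 10^4,$$

where $k^\*$ is the DFT bin nearest $f_{stim}$. The $2/X(0)$ normalization
makes a noise-free cosine of fractional amplitude $a$ spanning an integer
number of cycles map to exactly $a \times 10^4$ — the "fractional change in
reflection × 10⁴" convention of published magnitude maps. The acquisition
defaults guarantee an exact bin (0.12 Hz × 300 s = 36 cycles); off-bin
leakage beyond 1% of the bin spacing triggers a warning. The phase map is
retained but unused: the OD pipeline averages magnitudes of the two drift
directions, it does not perform phase-based hemodynamic-delay correction.

## The ODI pipeline and its choices

The pipeline order is: per-stack Fourier maps → direction average per eye →
5 × 5 Gaussian smoothing → ROI from the smoothed ipsilateral map → ROI
amplitudes and pixelwise ODI. Choices worth knowing:

* **Gaussian σ.** Only the 5 × 5 extent of the low-pass kernel is
  conventional; σ is not. Default σ = 1 px, kernel renormalized to unit sum;
  configurable via `smooth_map(sigma=)`. Borders use half-sample symmetric
  reflection, which conserves the map sum exactly for any symmetric kernel
  (asserted in the tests).
* **ROI connectivity.** "Pixels above 30% of the ipsilateral peak" does not
  say whether disconnected supra-threshold islands count. Default: the
  8-connected component containing the peak pixel, which excludes detached
  noise blobs; `connected = FALSE` keeps all supra-threshold pixels.
* **ODI definition.** The ODI is the ROI mean of the *pixelwise*
  $(C-I)/(C+I)$, not the ratio of ROI-mean amplitudes; the two differ and
  the tests pin the pixelwise definition. Because each eye's map is smoothed
  with the same kernel, ROI-edge pixels whose amplitudes are attenuated by
  smoothing keep their ratio — the ODI is robust to the exact ROI halo,
  while raw amplitude is not (see "amplitude truth" below).
* **Histogram.** The per-pixel ODI histogram uses 50 equal bins on
  $[-1, 1]$; bin count is a reporting choice with no downstream effect.
* **Registration.** Before/after sessions are assumed co-registered (rigs
  align by the vasculature image); no registration is implemented, and the
  ROI is re-derived independently per session since sessions are imaged on
  different days. A frozen-ROI sensitivity mode can be built from the stage
  outputs retained in `session_analysis`.

## What the imaging generator emulates — and what it does not

`imaging_truth()` stakes out an elliptical binocular zone (~800 px of a
64 × 64 field) carrying uniform per-eye amplitudes, default 2.5 × 10⁻⁴
(contra) and 1.3 × 10⁻⁴ (ipsi) — the magnitude and ~0.3 ODI of a naive
adult mouse — with zero modulation outside the zone. Per-frame noise is
white Gaussian with SD 10⁻³ in units of the baseline reflectance: the
shot-noise scale of roughly 10⁶ detected photons per pixel per frame, which
puts single-frame SNR at ~0.1 and makes the 5-minute Fourier integration do
the work, exactly the regime the technique operates in. The 0.12 Hz sweep
frequency is an assumption (the acquisition convention fixes only the 5 min
per direction); it was chosen to give an integer 36 cycles and is
configurable.

Not emulated: vasculature artifacts, hemodynamic response convolution
(the phase offset is a free parameter per direction, not a model), slow
physiological drift, motion, or spatially correlated noise. A green
parameter-recovery test therefore establishes estimator correctness under
the stated statistical structure, not robustness to those artifacts.

One consequence of the noise floor: the magnitude of a non-responsive pixel
is Rayleigh-distributed with mean $\sigma_a\sqrt{\pi/2}$, where
$\sigma_a = \sigma_\varepsilon \sqrt{2/T}$ is the amplitude uncertainty
after $T$ frames. At reduced acquisition scales this floor approaches the
30% ROI threshold; the reduced-scale recovery test therefore scales
$\sigma_\varepsilon$ by $\sqrt{T_{reduced}/T_{full}}$ so the per-pixel
amplitude uncertainty matches the full-scale setting, and the full-scale
claim is tested at full scale in the acceptance suite.

**Amplitude truth.** Recovery tests compare the recovered ROI amplitude to
the mean over the recovered ROI of the *smoothed* true amplitude map. This
isolates estimator accuracy from ROI-edge geometry: the ROI legitimately
includes a ~1 px halo where smoothing attenuates both eyes equally, which
leaves the ODI invariant but lowers raw amplitudes relative to the unsmoothed
zone value.

# Sr²⁺-desynchronized quantal EPSC analysis

## Windows and the correction formula

Sweeps are 1500 ms with stimulation at 700 ms and a 100 ms seal-test pulse
(excluded from all analysis, with a settling margin). Spontaneous events are
quantified in [300, 700) ms ("pre"), evoked activity in [750, 1150) ms
("post"; 400 ms after a 50 ms delay), events assigned by onset time with
half-open windows. The corrected evoked quantal amplitude is

$$\frac{A_{post} f_{post} - A_{pre} f_{pre}}{f_{post} - f_{pre}},$$

which is algebraically exact — equal to the mean amplitude of the evoked
events — whenever the spontaneous process contributes identically to both
windows (a property test asserts this identity on arbitrary event sets).
Cells whose post rate does not exceed the pre rate carry no information about
evoked amplitude and are flagged `no_rate_increase` rather than estimated.

## RMS noise estimation and the 2 pA exclusion

The conventional exclusion rule is "RMS noise > 2" (interpreted as 2 pA, the
natural unit for these voltage-clamp currents; configurable). The estimator
must not be inflated by the very spontaneous events the recording contains,
so each sweep contributes the successive-difference estimate
$1.4826 \cdot \mathrm{median}\,|x_{t+1}-x_t| / \sqrt{2}$ over the baseline
segment (everything outside the test pulse and the 0.65–1.2 s peri-stimulus
region). Successive differencing annihilates the slow synaptic waveforms
(millisecond-scale rise, ~6 ms decay) while the scaled median of absolute
differences is unbiased for white Gaussian noise; a plain SD would be
inflated several percent by 1 Hz spontaneous activity and, at the knife-edge
cutoff, would exclude nearly every 2 pA-noise cell. The cell-level estimate
is the median across sweeps. Note the stated world of the reference cell
puts the true RMS *exactly at* the cutoff, so an unbiased estimator excludes
roughly half of such cells by sampling alone; recovery statistics are
computed over the included subset, which is random with respect to event
amplitudes.

## Event detection

The detection convention fixes only the threshold (3 × RMS) and the rise-time
limit (3 ms); the detector itself is this package's design:

* Detection trace: brick-wall FFT low-pass at 1 kHz. Candidate events are
  its local minima; minima closer than 2 ms are merged keeping the deeper
  (overlapping events ≥ 2 ms apart count separately).
* Local baseline: median of the filtered trace over [−7, −1] ms before the
  peak, then re-anchored to the 5 ms preceding the provisional 10% crossing
  — without this second pass, slow-rising events are measured against their
  own rising phase and their rise times are underestimated.
* Same-event suppression: processing candidates deepest-first, a shallower
  minimum within 8 ms of an accepted peak is treated as the same event
  (noise-split peak, mid-rise dip, or decay bump) unless the trace recovers
  above baseline − 0.6 × amplitude between the two peaks. Genuinely separate
  overlapping events recover past this level; decay bumps do not.
* Rise time: 10–90% on the filtered trace; events above 3 ms are excluded.
* Amplitude: baseline-to-peak on a lightly smoothed copy of the *raw* trace
  (Gaussian σ = 0.3 ms, minimum within ±0.1 ms of the filtered peak), so the
  detection filter does not attenuate reported amplitudes. The σ/window pair
  was calibrated on simulated isolated events to near-zero net bias — wider
  search windows select noise minima (positive bias), heavier smoothing
  attenuates the peak (negative bias). The residual bias is under 1% and the
  suite's unbiasedness test bounds it at 2%.

False positives are negligible by construction: the filtered noise SD is
~0.45 × RMS, so the 3 × RMS threshold sits at ~6.7 filtered-noise SDs.

## The ephys generator

Events are difference-of-exponentials inward currents, amplitude-normalized
analytically, with 10–90% rise solved numerically from the (rise, decay)
pair — defaults 1 ms and 6 ms, safely inside the 3 ms inclusion limit.
Spontaneous events are Poisson over the whole sweep; evoked events are
Poisson within 750–1150 ms, mirroring the post window so generated events
are capturable by the stated analysis. Amplitudes are lognormal (mean 12 pA
spontaneous, 18 pA evoked, CV 0.25 — a typical quantal amplitude spread);
baseline noise is white Gaussian. The reference cell (1 Hz spontaneous,
evoked rate 7 ev/s so the post-window total is 8 ev/s, RMS 2 pA, 60 sweeps)
is the default `ephys_truth()`. Deterministic event injection (`events=`)
supports ground-truth detector tests. Not emulated: stimulus artifacts,
capacitive transients, series-resistance errors, multivesicular or
correlated release, 1/f noise.

# STDP quantification

EPSP strength is the initial slope: a least-squares fit of voltage against
time over the first 2 ms from onset. Onset is the first point after the
stimulus where voltage exceeds the pre-stimulus baseline mean + 2 SD and
stays above it for 0.5 ms (an explicit choice; the convention does not define
onset detection), with a warning above the 4 ms monosynaptic latency limit.
Baseline strength is the mean of the last 30 pre-drug sweeps. The reported
plasticity magnitude is the mean slope in a 25–30 min post-pairing window as
a percent of baseline — the endpoint window is a choice (reports quote
"~30 min after induction" without a precise window) and is configurable.
Slopes are normalized per cell before any cross-cell averaging.

The generator produces sweeps every 20 s with a linear rising phase (3 ms at
the target slope, peaks in the 2–10 mV monosynaptic range) after a 2 ms
latency; the pairing multiplies the slope by `post_ratio` as a stable step.
Noise enters as per-sweep multiplicative slope jitter (default 5%) and
additive trace noise (default 0.1 mV). Not emulated: gradual plasticity
expression, rundown, temperature or access drift — so recovery tests
establish the estimator chain, not robustness to slow nonstationarities.

# Determinism and reproducibility

All generators derive sub-stream seeds deterministically from one top-level
seed (a string-hash of seed plus stream labels), so any single stack or
sweep set can be regenerated without replaying the whole session. Imaging
noise uses a self-contained xoshiro256++/ziggurat normal sampler in C++
(bit-reproducible for a given seed independent of the C++ standard library,
and fast enough for the ~1.5 × 10⁸ samples of a full session);
electrophysiology generators use R's RNG under a save/restore wrapper so
callers' RNG state is never disturbed. `run_pipeline()` output is a pure
function of (config, seed): reruns are byte-identical, which the acceptance
suite asserts.

# File formats

Stacks and sweeps move through a CSV-matrix + JSON-sidecar schema
(`frame_rate_hz`, `stim_freq_hz`, `eye`, `direction_deg`;
`sampling_rate_hz`, `stim_onset_s`, test-pulse window). Production rigs
would use TIFF or HDF5 with the same metadata; no R reader for those formats
is available in this build environment, so the text schema is the supported
interchange and binary readers can be slotted in behind the same functions.

# Known limitations

* No image registration, vessel masking, or hemodynamic modeling; the
  imaging analysis assumes pre-registered, artifact-free stacks.
* The quantal detector is calibrated for ~1 ms rise / ~6 ms decay kinetics
  on white noise at 5–20 kHz sampling; heavily filtered or correlated-noise
  recordings would need the cutoff and measurement-window parameters
  revisited.
* Inferential statistics in group summaries (paired Wilcoxon) are thin
  wrappers over `stats::wilcox.test`, reported for transparency and labeled
  as routine; the package's contribution is the measurement pipeline.
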