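{
  "seed": 1,
  "imaging": {
    "n_sessions": 2,
    "height": 32,
    "width": 32,
    "duration": 50,
    "frame_rate": 10,
    "stim_freq": 0.12,
    "noise_sd": 0.001,
    "odi_before": 0.3,
    "odi_after": 0.1,
    "roi_fraction": 0.3
  },
  "quantal": {
    "n_cells": 3,
    "n_sweeps": 30,
    "noise_rms": 1.5
  },
  "stdp": {
    "post_ratios": [0.6, 1.0, 1.235],
    "slope_jitter_sd": 0.05,
    "trace_noise_mv": 0.1
  }
}
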