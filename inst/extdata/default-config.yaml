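# msimg default configuration.
# Thresholds marked "no published default" are dataset-dependent choices;
# the values here are the package defaults used throughout the documentation.

binning:
  mz_min: 100.0        # Da; REQUIRED per study, no published default
  mz_max: 1100.0       # Da; REQUIRED per study, no published default
  bin_size: 0.1        # Da; no published default

normalization:
  percentile: 99.9     # upper percentile of non-zero intensities -> 1.0

density:
  tau_intensity: 0.01  # signal-mask threshold; no published default
  window: 9            # odd box-window side w; no published default
  tau_density: 5       # minimum density of an NMS peak; no published default
  max_peaks: 100       # per-sample NMS budget; no published default

selection:
  patch_height: 224    # pixels (224 suits common CNN backbones)
  patch_width: 224
  tau_min_peaks: 2     # greedy-coverage stop; no published default
  num_patches: 64      # image channel count

patch:
  pad_value: 0.0       # fill for out-of-bounds patch cells
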