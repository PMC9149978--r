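# Demo configuration for the end-to-end CT-to-MR synthesis pipeline on the
# built-in digital phantom pair (train on layout A, synthesize layout B).
seed: 42
phantom:
  shape: 64
ct:
  noise_sd: 5        # per-acquisition CT noise, HU
  n_repeats: 9       # repeated acquisitions averaged before feature extraction
mr:
  noise_sd: 9        # MR signal noise, a.u. (about 1% of peak signal)
  te_fixed: 20       # TE of the variable-TR series, ms
  tr_fixed: 2000     # TR of the variable-TE series, ms
segmentation:
  n_clusters: 2
mapping:
  mode: piecewise_linear   # or: nearest
  fallback: nearest
  window_size: 5
  min_count: 6
weightings:
  - {name: t1w, te: 10,  tr: 500}
  - {name: t2w, te: 130, tr: 2000}
  - {name: pdw, te: 10,  tr: 4000}
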