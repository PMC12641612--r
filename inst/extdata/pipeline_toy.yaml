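outdir: scratch/pipeline-run
seed: 1
sim:
  contig_length: 6000
  coverage_min: 2
  coverage_max: 6
  variant_rate: 0.005
  n_subjects: 2
filtration:
  reduction_factor: 2
packing:
  strategy: consecutive
  context_length: 256
weighting:
  mode: dynamic
model:
  n_layers: 1
  d_model: 16
  n_heads: 2
train:
  steps_phase1: 6
  steps_phase2: 6
  batch_size: 2
  mix_ratio: 0.5
eval:
  strategies: [consecutive, reference]
tasks:
  window: 21
  controls: 40
  folds: 3
  probe: true
  probe_hidden: 8
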