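output_root: mm_run
seed: 1.0
synthgen:
  n_species: 8.0
  n_genera: 7.0
  n_families: 4.0
  n_orders: 3.0
  n_per_species: 12.0
  n_frames: 16.0
  img_size:
  - 80.0
  - 80.0
  px_per_mm: 4.5
  junk_rate: 0.05
  failure_rates:
  - 0.072
  - 0.034
  - 0.031
  p_repeat: 0.27
  write_images: yes
features:
  threshold: auto
  area_bounds:
  - 2.0
  - 200.0
  solidity_bounds:
  - 0.0
  - .inf
assign:
  min_reads: 1000.0
build:
  k: 5.0
  min_specimens_per_species: 5.0
models:
  input_size: 64.0
  channels:
  - 6.0
  - 12.0
  - 24.0
  batch_size: 32.0
  lr: 0.01
  transform: log1p
  classifier:
    rank: species
    epochs: 20.0
  scratch:
    epochs: 22.0
  finetune:
    epochs: 10.0
  enabled:
  - classifier
  - linear
  - mean
  - cnn_scratch
  - ft_unfrozen
  - ft_frozen
  linear_sets:
  - P
  - A
  - MFD
  - - A
    - MFD
    - P
evaluate:
  ranks:
  - species
  - genus
  - family
  - order
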