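# Default pipeline configuration.
# Training defaults follow the reference recipe (100 epochs, 5 warm-up,
# Adam at peak rate 5e-5, 224x224 inputs, crop/flip/jitter augmentation);
# backbone and synthetic-data defaults are sized for desk-scale runs.

backbone:
  family: nf_resnet      # nf_resnet (normalization-free) or resnet (BN baseline)
  depth: 26              # 26 / 50 / 101
  width_multiplier: 0.125

attention:
  enabled: true
  r: 4                   # channel reduction ratio of the pointwise conv
  r2: 16                 # bottleneck ratio of the channel-attention MLP

train:
  epochs: 100
  warmup_epochs: 5
  peak_lr: 0.00005
  batch_size: 32
  image_size: 224
  seed: 1

synthetic:
  n: 200
  class_balance: 0.5
  image_size: 64
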