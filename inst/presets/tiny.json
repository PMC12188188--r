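{
  "name": "tiny",
  "description": "Desk-scale preset: two conv layers at 24 channels with one residual skip (~24 k trainable parameters); trains on a CPU in seconds per epoch.",
  "conv_channels": [24, 24],
  "kernel_sizes": [9, 11],
  "residual_after": [2],
  "batchnorm": true,
  "maxpool": true,
  "pool_width": 5,
  "fc_dims": [32],
  "dropout": [0],
  "train": {
    "loss": "L1",
    "optimizer": "AdamW",
    "learning_rate": 0.003,
    "weight_decay": 0.0001,
    "batch_size": 128
  }
}
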