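{
  "name": "camformer_mini",
  "description": "Compact CNN without residual connections (1.4 M trainable parameters with 4-channel input).",
  "conv_channels": [64, 128, 128, 64],
  "kernel_sizes": [9, 7, 7, 5],
  "residual_after": [],
  "batchnorm": true,
  "maxpool": true,
  "pool_width": 2,
  "fc_dims": [320, 128],
  "dropout": [0.1, 0.1],
  "train": {
    "loss": "L1",
    "optimizer": "AdamW",
    "learning_rate": 0.001,
    "weight_decay": 0.01,
    "batch_size": 128
  }
}
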