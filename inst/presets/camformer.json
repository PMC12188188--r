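{
  "name": "camformer",
  "description": "Full model: six conv layers at 512 channels, residual skips after layers 2/4/6, penultimate max pooling, three fully connected layers (16.6 M trainable parameters with 4-channel input).",
  "conv_channels": [512, 512, 512, 512, 512, 512],
  "kernel_sizes": [15, 7, 7, 7, 7, 7],
  "residual_after": [2, 4, 6],
  "batchnorm": true,
  "maxpool": true,
  "pool_width": 2,
  "fc_dims": [256, 512],
  "dropout": [0.2, 0.2],
  "train": {
    "loss": "L1",
    "optimizer": "AdamW",
    "learning_rate": 0.001,
    "weight_decay": 0.01,
    "batch_size": 128
  }
}
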