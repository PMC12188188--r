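{
  "name": "camformer_small",
  "description": "Halved-width variant: the camformer residual trunk at 256 channels with a reduced fully connected head (3.4 M trainable parameters with 4-channel input).",
  "conv_channels": [256, 256, 256, 256, 256, 256],
  "kernel_sizes": [15, 7, 7, 7, 7, 7],
  "residual_after": [2, 4, 6],
  "batchnorm": true,
  "maxpool": true,
  "pool_width": 4,
  "fc_dims": [160, 96],
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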