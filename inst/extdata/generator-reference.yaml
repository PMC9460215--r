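name: generator
input_shape:
  length: 10000.0
  channels: 1.0
layers:
- layer_type: fully_connected
  activation: none
  out_channels: 64
  out_length: 2500.0
- layer_type: upsample
  activation: none
  upsample_factor: 2
- layer_type: conv1d
  activation: ReLU
  kernel: 3
  stride: 1
  padding: 1
  out_channels: 64
- layer_type: batch_norm
  activation: none
  momentum: 0.8
- layer_type: upsample
  activation: none
  upsample_factor: 2
- layer_type: conv1d
  activation: ReLU
  kernel: 3
  stride: 1
  padding: 1
  out_channels: 32
- layer_type: batch_norm
  activation: none
  momentum: 0.8
- layer_type: conv1d
  activation: Tanh
  kernel: 3
  stride: 1
  padding: 1
  out_channels: 1

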