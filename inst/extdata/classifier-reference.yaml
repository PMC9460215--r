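name: classifier
input_shape:
  length: 10000.0
  channels: 1.0
layers:
- layer_type: conv1d
  activation: LeakyReLU
  alpha: 0.2
  kernel: 8
  stride: 4
  padding: 2
  out_channels: 64
- layer_type: conv1d
  activation: LeakyReLU
  alpha: 0.2
  kernel: 8
  stride: 4
  padding: 0
  out_channels: 64
- layer_type: conv1d
  activation: LeakyReLU
  alpha: 0.2
  kernel: 8
  stride: 4
  padding: 0
  out_channels: 64
- layer_type: conv1d
  activation: LeakyReLU
  alpha: 0.2
  kernel: 8
  stride: 4
  padding: 0
  out_channels: 1
- layer_type: fully_connected
  activation: Softmax
  out_channels: 3
  out_length: 1

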