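# Desk-scale end-to-end profile (see ?quicktestConfig and the vignette).
dataset:
  train: 300
  val: 40
  test: 40
  nx: 128
  ny: 96
  seed: 11
network:
  depth: 3
  baseChannels: 16
train:
  learningRate: 0.002
  batchSize: 12
  epochs: 24
  seed: 7
  lrDecayAt: [15, 21]
gamma:
  criteria:
    - [3, 3]
    - [2, 2]
  thresholdPercent: 5
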