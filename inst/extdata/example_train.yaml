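# Canonical training configuration. layer_sizes starts with the input
# dimension; omit it to use the default d -> min(200, ceiling(d/2)).
seed: 1
layer_sizes: [500, 200]
dae:
  epochs: 10
  learning_rate: 0.05
  loss: cross_entropy
  v: 0.3
bpmll:
  M: 32
  alpha: 0.05
  max_epochs: 50
  patience: 3
cv:
  k: 10
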