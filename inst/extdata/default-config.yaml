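# Full study configuration: every omitted key falls back to the same
# defaults, so an empty file is equivalent. Values shown for reference.
cost:
  rho: 3000
  upsilon: 1
  gamma: 0.6
  w_perp: 1
  timeout: 4
estimator:
  delay: 10
  k1: 0.2
  k2: 1.0
optimizer:
  sigma0: 0.01
  popsize: 30
  max_iter: 5000
  repet: 50
task:
  widths: [0.005, 0.01, 0.02, 0.04]
  n_hidden: 10
seed: 1
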