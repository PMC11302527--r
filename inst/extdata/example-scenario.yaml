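name: example
network:
  family: ba
  'n': 200.0
  m: 10.0
fraction_anti: 0.15
target_corr: 0.0
base_composition:
  name:
  - conf_o10
  - conf_o-10
  delta_o:
  - 10.0
  - -10.0
  w:
  - 1.0
  - 1.0
  frac:
  - 0.5
  - 0.5
anti_w: -1.0
anti_delta_o: ~
schedule: ~
beta: 100.0
initial_fraction_A: 1.0
init_mode: random
horizon: 500.0
record_every: 1.0
quiet_sweeps: 50.0
assortative_mode: ~
assortative_steps: ~
assortative_target_r: ~
realizations: 5.0
seed: 1.0
placement_tolerance: 0.01
placement_max_iters: 1000000.0
thresholds:
  alignment: 0.9
  tipping: 0.5
  burn_in: 100.0
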