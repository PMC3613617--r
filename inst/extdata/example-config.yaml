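# Example configuration for the rchp command-line runner.
# Omitted fields keep the package defaults; see ?network_params,
# ?plasticity_params, ?classical_config, ?operant_config, ?toy_config.
network:
  n_excitatory: 800
  n_inhibitory: 200
  connect_prob: 0.1
  gain: 0.5
  dt: 0.2
plasticity:
  alpha: 0.1
  beta: 0.1
  tau_c: 4
  tau_m: 1
  lambda: 0.25
  baseline: -0.001
  mu_target: 0.005
  eta: 0.002
  window: 10
classical:
  n_stimuli: 9
  cs_index: 1
  appear_prob: 0.0015
  total_time: 7200
operant:
  n_colors: 5
  n_actions: 8
  period: 20
  reward_correct: 5
  reward_wrong: -0.5
  total_time: 1800
toy:
  n_synapses: 100000
  corr_rate: 0.01
  eligibility_horizon: 3
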