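# Reference experiment configuration.
# Units: time ms, rates Hz, currents nA except I0_pA (picoamperes).
model:
  a: 270            # f-I gain (Hz/nA)
  b: 108            # f-I offset (Hz)
  d: 0.154          # f-I curvature (s)
  gamma: 0.641      # synaptic coupling factor
  tau_S: 100        # NMDA gating time constant (ms)
  tau_noise: 2      # noise-current correlation time (ms)
  J_self: 0.2609    # recurrent self-coupling (nA)
  J_cross: 0.0497   # cross-inhibition (nA)
  J_ext: 0.00052    # external input scaling (nA/Hz)
  mu0: 30           # stimulus reference rate (Hz)
conditions:
  speed:    {I0_pA: 325, sigma_noise: 0.02}
  neutral:  {I0_pA: 321, sigma_noise: 0.02}
  accuracy: {I0_pA: 316, sigma_noise: 0.02}
schedule:
  t_prestim_ms: 2500
  t_stim_ms: 5000
  dt_ms: 0.1
task:
  coherences_pct: [0, 1, 2, 4, 8, 16, 32]
  n_trials: 1000
  theta_hz: 15      # choice threshold
  sustain_ms: 2     # rate must stay above theta this long (noise-spike guard)
sweep:
  theta_grid_hz: [9, 10, 11, 12, 13, 14, 15, 16, 17, 18, 19, 20, 21]
observer:
  criterion: 0.75   # ROC AUC criterion for ideal-observer discrimination
  sustain_bins: 3   # consecutive bins the criterion must hold
  bin_ms: 10        # trace bin width for the AUC time course
  smooth_ms: 50     # moving-average window for last-intersection analysis
seed: 1
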