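# Example analysis configuration for the reference finger-tapping protocol.
protocol:
  preparation_s: 42
  n_sessions: 10
  task_s: 21
  rest_s: 30
  sampling_rate_hz: 1.81

mbll:
  wavelengths_nm: [760, 830]
  # the study text prints a 2 mm optode distance, which is anomalously small
  # for topography; distance is therefore a required user input, recorded
  # here as printed
  distance_mm: 2
  dpf: [6.0, 6.0]
  reference_index: 1

hrf:
  peak_delay_s: 6
  undershoot_delay_s: 16
  peak_dispersion_s: 1
  undershoot_dispersion_s: 1
  undershoot_ratio: 6
  kernel_length_s: 32

design:
  n_dct: 3            # task + baseline + 3 DCT columns -> L = 5
  # dct_cutoff_hz: 0.0006   # alternative specification mode

kalman:
  q: 1.0e-04           # (1%/sec)^2
  r: 0.25             # (0.5 uM/sec)^2
  p0: 1.0e+04

ar:
  enabled: true
  burn_in: 30
  # fixed_rho: 0.3    # optional: freeze rho from training data

test:
  p_in: 0.05
  j_policy: cumulative
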