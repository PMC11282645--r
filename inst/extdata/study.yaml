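# Example study configuration: defaults mirror the eight-protocol
# three-repetition design; any scalar can be overridden.
repetitions: 3
base_seed: 1
noise_free: false
protocol_csv: protocols.csv
waveform:
  heart_rate: 120
  amplitude_ratio: 0.52
  frequency_ratio: 4.29
  target_stroke_volume: 0.2597
transport:
  dispersion_factor: 0.012
  production_rate: 0.018
  absorption_rate: 0.018
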