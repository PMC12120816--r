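# Example configuration for `hipposlice pipeline` / run_pipeline().
# Reduced scale for a quick demonstration run; the full recording regime
# is lfp_duration_s: 120 at fs_hz: 10000.
n_per_group: 6
lfp_duration_s: 20
fs_hz: 2000
sw_rate_hz:
  a: 0.2
  b: 0.4
gamma_freq_hz:
  a: 40
  b: 40
spine_mix:
  mushroom: 10
  thin: 8
  stubby: 5
  long_thin: 4
seed: 21
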