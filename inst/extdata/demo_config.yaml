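# Demonstration configuration for the full vocalarm pipeline.
# Any key omitted here is filled from vocalarm::default_config().
output_dir: demo_out
seed: 7
corpus:
  n_speakers: 4
  instances_per_type: 2
mps:
  n_perm: 200
alarmsplit:
  n_raters: 23
  n_per_type: 60
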