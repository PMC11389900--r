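# Example run configuration for the command-line wrapper
task:
  n_blocks: 5
  trials_per_block: 24
n_per_group: 10
groups: [younger, older]
mode: power
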