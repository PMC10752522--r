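# Hypoxic sickle-cell retention in a Couette microchannel.
domain:
  h: 20
cells:
  count: 12
  shape: biconcave
  hct: 0.02
  condition: sickle_hypoxia
adhesion: hypoxia
aggregation:
  enabled: true
macrophages:
  count: 2
  radius: 9
velocity: 150
seed: 1
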