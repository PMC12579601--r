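primaries:
  red:
  - 0.6847
  - 0.3111
  - 26.4
  green:
  - 0.2138
  - 0.7263
  - 69.9
  blue:
  - 0.1521
  - 0.0453
  - 4.8
gamma: 2.2
white:
- 0.3304
- 0.3526
- 101.1
background_Lstar: 70.0
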