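# Intensity protocol: DD, then the 15-h window at 100 lux, the same window
# at 1,000 lux, and release into DD.
seed: 1
pulse_duration_hours: 1
behavior:
  dispersion: 5
stages:
  - type: dd
    days: 40
  - type: random
    I_hours: 15
    L_lux: 100
    days: 40
  - type: random
    I_hours: 15
    L_lux: 1000
    days: 40
  - type: dd
    days: 40
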