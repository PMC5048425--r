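# Decreasing-dispersion protocol: DD, then random single daily pulses in
# windows of 20 h, 15 h and 8 h at 1,000 lux.
seed: 1
pulse_duration_hours: 1
behavior:
  dispersion: 5
stages:
  - type: dd
    days: 40
  - type: random
    I_hours: 20
    L_lux: 1000
    days: 40
  - type: random
    I_hours: 15
    L_lux: 1000
    days: 40
  - type: random
    I_hours: 8
    L_lux: 1000
    days: 40
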