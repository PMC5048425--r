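# Increasing-dispersion protocol: DD, fixed daily pulse (LD1:23), then
# random single daily pulses in windows of 8 h, 8 h delayed by 6 h, 15 h
# and 20 h, all at 1,000 lux.
seed: 1
pulse_duration_hours: 1
behavior:
  dispersion: 5
stages:
  - type: dd
    days: 40
  - type: fixed
    pulse_time: 12
    L_lux: 1000
    days: 40
  - type: random
    I_hours: 8
    L_lux: 1000
    days: 40
  - type: random
    I_hours: 8
    L_lux: 1000
    days: 40
    shift: 6
  - type: random
    I_hours: 15
    L_lux: 1000
    days: 40
  - type: random
    I_hours: 20
    L_lux: 1000
    days: 40
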