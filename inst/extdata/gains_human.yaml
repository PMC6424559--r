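fp_x:
  left: 0.95
  right: 1.0
fp_y:
  left:
    vy: 0.42
    za: -0.76
  right:
    vy: 0.39
    za: -0.83
landing: 0.3
K_right:
  vx:
  - -0.05
  - -0.02
  - 0.31
  vy:
  - -0.08
  - 0.27
  - -0.15
  za:
  - 0.02
  - 0.06
  - 0.46
K_signif:
- - no
  - no
  - no
- - no
  - yes
  - no
- - no
  - yes
  - yes
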