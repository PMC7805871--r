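# Default controller configuration: published virtual-muscle constants,
# ankle geometry and the two tuned subject activation profiles.
muscle:
  anterior:
    P0: 1799.0        # peak isometric force, N
    kts: 159.0        # titin spring constant, N/cm
    kss: 1499.0       # series spring constant, N/cm
    Cce_l: 97.0       # CE damping, lengthening, N.s/cm
    Cce_s: 182.0      # CE damping, shortening, N.s/cm
    fl_width: 0.5     # force-length half-width, fraction of L0
  posterior:
    P0: 1654.0
    kts: 205.0
    kss: 1559.0
    Cce_l: 102.0
    Cce_s: 57.0
    fl_width: 0.5
geometry:
  SAL_A: 29.0         # anterior shank attachment length, cm
  SAL_P: 33.0         # posterior shank attachment length, cm
  FMA_A: 4.0          # anterior foot moment arm, cm
  FMA_P: 5.5          # posterior foot moment arm, cm
  gamma0_A: 90.0      # included shank-foot angle at neutral, deg
  gamma0_P: 90.0
schedule:
  profile1:
    act_A: [0.93, 0.28, 0.31, 0.0, 0.0]   # stages 2..6
    act_P: [0.0, 0.0, 0.0, 0.0, 0.44]
  profile2:
    act_A: [0.63, 0.48, 0.51, 0.0, 0.0]
    act_P: [0.0, 0.0, 0.0, 0.0, 0.69]
controller:
  sample_rate_hz: 500.0
  resistance_gain: 0.0     # N.m.s/deg, viscous compensation (0 = pure model)
  constant_arm: false      # use constant foot moment arms instead of dL/dtheta
  smoothing_window: 0      # activation ramp window, samples (0 = square wave)
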