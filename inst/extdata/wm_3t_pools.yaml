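# Synthetic stand-in for the public 3 T white-matter Bloch-McConnell pool set
# (pulseq-cest-library sim-library, WM_3T_001_bmsim.yaml). Values mirror the
# published 3 T white-matter literature: water relaxometry and the semisolid
# magnetization-transfer pool from quantitative MT measurements at 3 T
# (T1w 1.084 s, T2w 69 ms; bound-pool fraction 13.9%, T2b ~ 10 us, exchange
# 23 /s), plus a standard amide pool (~72 mM exchangeable amide protons,
# +3.5 ppm, ~30 /s at physiological pH).
water_pool:
  f: 1.0
  t1: 1.084
  t2: 0.069
mt_pool:
  f: 0.139
  t1: 1.0
  t2: 9.6e-6
  k: 23.0
  dw: 0.0
  lineshape: superlorentzian
cest_pool:
  amide:
    f: 6.49e-4
    t1: 1.0
    t2: 0.01
    k: 30.0
    dw: 3.5
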