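# Static file spanning the elongation zone: lengths grow linearly from
# 20 um to 200 um over 20 cells, vacuolar fractions from 0.1 to 0.9.
preset: ga_short
plasmodesmata: false
profile:
  kind: linear_space
  l1_um: 20
  lN1_um: 200
  phi1: 0.1
  phiN1: 0.9
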