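{
  "name": "molecule II",
  "handedness": "S",
  "dipole_debye": 10.9,
  "l_rev_angstrom": 0.18,
  "d_r_deg2_s": 8200000000000,
  "d_trans_cm2_s": 1.4e-05
}
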