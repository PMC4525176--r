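{
  "name": "molecule I",
  "handedness": "S",
  "dipole_debye": 5.3,
  "l_rev_angstrom": 1.22,
  "d_r_deg2_s": 3988140000000,
  "d_trans_cm2_s": 8.3e-06,
  "d_r_note": "inferred: back-solved from the 0.507 MHz escape frequency at 6e5 V/m, 293 K (not directly published)"
}
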