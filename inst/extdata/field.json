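{
  "e_v_m": 600000,
  "nu_hz": 900000,
  "sense": "CW",
  "temperature_k": 293,
  "eta_pa_s": 0.0065
}
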