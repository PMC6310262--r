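{
  "id": "median-hd1",
  "V_P0": 3.2,
  "ECV0": 16.3,
  "ICV0": 14.5,
  "tp_gdl": 6.5,
  "na": 140,
  "k": 5.6,
  "urea": 55.2,
  "glucose": 4.7,
  "MAP": 93,
  "duration": 238,
  "Qb": 265,
  "Juf": 11.5,
  "D_na": 220.9,
  "D_k": 153.7,
  "D_urea": 220.9,
  "Cd_na": 142,
  "Cd_k": 3,
  "Cd_urea": 0,
  "ramp": "none",
  "variant": "baseline"
}
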