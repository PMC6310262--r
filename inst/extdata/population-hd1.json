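{
  "session": "hd1",
  "quantities": [
    {
      "name": "duration",
      "median": 238,
      "q1": 234,
      "q3": 247
    },
    {
      "name": "Qb",
      "median": 265,
      "q1": 230,
      "q3": 320
    },
    {
      "name": "Juf",
      "median": 11.5,
      "q1": 9.6,
      "q3": 13.6
    },
    {
      "name": "ECV0",
      "median": 16.3,
      "q1": 14.4,
      "q3": 19.3
    },
    {
      "name": "ICV0",
      "median": 14.5,
      "q1": 12.1,
      "q3": 17
    },
    {
      "name": "V_P0",
      "median": 3.2,
      "q1": 2.8,
      "q3": 3.4
    },
    {
      "name": "MAP",
      "median": 93,
      "q1": 79.9,
      "q3": 110.5
    },
    {
      "name": "tp_gdl",
      "median": 6.5,
      "q1": 6.2,
      "q3": 6.7
    },
    {
      "name": "na",
      "median": 140,
      "q1": 138.5,
      "q3": 142.5
    },
    {
      "name": "k",
      "median": 5.6,
      "q1": 5.4,
      "q3": 6.1
    },
    {
      "name": "glucose",
      "median": 4.7,
      "q1": 4,
      "q3": 5.9
    },
    {
      "name": "urea",
      "median": 55.2,
      "q1": 44.9,
      "q3": 67.6
    },
    {
      "name": "D_urea",
      "median": 220.9,
      "q1": 139.6,
      "q3": 232.4
    },
    {
      "name": "D_k",
      "median": 153.7,
      "q1": 129.5,
      "q3": 176.5
    },
    {
      "name": "Cd_na",
      "median": 142,
      "q1": 140.8,
      "q3": 144
    },
    {
      "name": "Cd_k",
      "median": 3,
      "q1": 2.1,
      "q3": 3.1
    }
  ],
  "noise": {
    "pv": 0.05,
    "tp": 0.2,
    "na": 0.2,
    "k": 0.2,
    "urea": 0.2
  }
}
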