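{
  "session": "hd3",
  "quantities": [
    {
      "name": "duration",
      "median": 240,
      "q1": 236,
      "q3": 253
    },
    {
      "name": "Qb",
      "median": 280,
      "q1": 240,
      "q3": 320
    },
    {
      "name": "Juf",
      "median": 9.2,
      "q1": 6.7,
      "q3": 10
    },
    {
      "name": "ECV0",
      "median": 15.5,
      "q1": 13.4,
      "q3": 17.5
    },
    {
      "name": "ICV0",
      "median": 15,
      "q1": 11.8,
      "q3": 17.9
    },
    {
      "name": "V_P0",
      "median": 3,
      "q1": 2.6,
      "q3": 3.3
    },
    {
      "name": "MAP",
      "median": 90.3,
      "q1": 80.7,
      "q3": 99
    },
    {
      "name": "tp_gdl",
      "median": 6.6,
      "q1": 6.4,
      "q3": 6.8
    },
    {
      "name": "na",
      "median": 140,
      "q1": 137,
      "q3": 142
    },
    {
      "name": "k",
      "median": 5.4,
      "q1": 5.1,
      "q3": 6.1
    },
    {
      "name": "glucose",
      "median": 4.7,
      "q1": 4,
      "q3": 5.5
    },
    {
      "name": "urea",
      "median": 46.2,
      "q1": 38.7,
      "q3": 52.1
    },
    {
      "name": "D_urea",
      "median": 201.3,
      "q1": 195.5,
      "q3": 226.4
    },
    {
      "name": "D_k",
      "median": 146.9,
      "q1": 120.7,
      "q3": 169.2
    },
    {
      "name": "Cd_na",
      "median": 142,
      "q1": 141,
      "q3": 143
    },
    {
      "name": "Cd_k",
      "median": 2.9,
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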