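{
  "toy_gate": {
    "generation": "hand transcription of the generator equations, 2026-10",
    "initial_rhs": {
      "V": -0.5,
      "m": -0.42459782363357
    },
    "rest_tau": {
      "m": 0.225865475358876
    },
    "rest_g_inf": {
      "m": 0.0040980107286595
    }
  },
  "hodgkin_huxley": {
    "generation": "hand transcription (helper-oracles.R), 2026-10",
    "initial_rhs": {
      "V": -0.600768750000001,
      "m": 0.0123855383553985,
      "h": -0.000455523906540065,
      "n": -0.00134157228632046
    },
    "rest_tau": {
      "m": 0.236766878685688,
      "h": 8.51601076440658,
      "n": 5.45858468751442
    },
    "rest_g_inf": {
      "m": 0.0529324852572496,
      "h": 0.59612075350846,
      "n": 0.317676914060697
    }
  },
  "luo_rudy_1991": {
    "generation": "hand transcription (helper-oracles.R), 2026-10",
    "initial_rhs": {
      "V": -0.000720864668557364,
      "m": -2.05341899928158e-07,
      "h": 2.82300343696588e-06,
      "j": 1.82451491268745e-06,
      "d": -1.90517302950974e-07,
      "f": 2.3931258967329e-07,
      "X": -0.000158620336486004,
      "Cai": -4.86053870794881e-09
    }
  },
  "singularity": {
    "generation": "hand transcription of the generator equations, 2026-10",
    "initial_rhs": {
      "V": 2.8,
      "g": -0.0215878741416131,
      "c": 5.9979878992172e-07
    }
  }
}
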