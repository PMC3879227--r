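{
  "name": "invitro",
  "target": "invitro_dose_response",
  "note": "synthetic ground truth, hand-tuned to the qualitative two-protocol dose-response features: immediate release under CRH, delayed strong release near 15 min under added cortisol, reduced 60-min level via genomic feedback",
  "verification": {
    "A_60min_nM": 31.0873946975034,
    "B_60min_nM": 22.2215564938582,
    "ratio_B_over_A": 0.714809224448867
  },
  "params": {
    "V_in": 1,
    "V_ex": 1,
    "V_nu": 1,
    "kdiff1": 0.2,
    "k1ex": 0.4,
    "k2in": 1,
    "k2ex": 0.05,
    "k3in": 0.2,
    "k3ex": 0.05,
    "d1": 0.06,
    "d2": 0.02,
    "d3": 0.01,
    "d4": 0.15,
    "d5": 0.01,
    "d6": 0.01,
    "d7": 0.01,
    "d8": 0.02,
    "d9": 0.05,
    "d10": 0.04,
    "d11": 0.05,
    "d12": 0.05,
    "d13": 0.05,
    "d14": 0.1,
    "d15": 0.1,
    "kGRC": 15,
    "kGRdim": 20,
    "kCRC": 5,
    "kGC2": 150,
    "K1": 10,
    "K3": 20,
    "K4": 5,
    "K5": 2,
    "K6": 4,
    "K7": 10,
    "K8": 0.4,
    "K9": 10,
    "v1": 5,
    "v2": 0.1,
    "v3": 0.1,
    "v4": 1,
    "v5": 0.02,
    "v6": 0.5,
    "v7": 0.01,
    "v8": 0.1,
    "ks": 10,
    "ksb": 0.1,
    "ktl1": 0.3,
    "ktl2": 0.5,
    "ktrs1": 0.2,
    "ktrs2": 0.2,
    "h": 2
  }
}
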