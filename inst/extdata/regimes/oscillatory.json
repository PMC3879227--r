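{
  "name": "oscillatory",
  "target": "hopf_oscillatory",
  "seed": 1,
  "n_starts": 40,
  "verification": {
    "kind": "reversible_bistable",
    "orientation": "hyper",
    "S1": 0.218099437275231,
    "S2": 0.158107950126464,
    "basal": 0.1,
    "period_min": 109.028571428571,
    "maxima_order": ["CRH", "ACTH_ex", "COR_ex"],
    "cycle_stress": 0.255468192979714
  },
  "params": {
    "V_in": 1,
    "V_ex": 1,
    "V_nu": 1,
    "kdiff1": 0.654235859434984,
    "k1ex": 1,
    "k2in": 5.39859095194764,
    "k2ex": 0.00949696104493867,
    "k3in": 0.2,
    "k3ex": 0.05,
    "d1": 0.0281337617608807,
    "d2": 0.0682189785649061,
    "d3": 0.05,
    "d4": 0.0253217801540595,
    "d5": 0.02,
    "d6": 0.01,
    "d7": 0.01,
    "d8": 0.116241657725518,
    "d9": 0.906365179407351,
    "d10": 0.05,
    "d11": 0.05,
    "d12": 0.05,
    "d13": 0.05,
    "d14": 0.1,
    "d15": 0.1,
    "kGRC": 1.47600155387443,
    "kGRdim": 3.41232732962255,
    "kCRC": 46.9920682210277,
    "kGC2": 3000,
    "K1": 25.5538052077347,
    "K3": 19.5501239195893,
    "K4": 2.36197325383021,
    "K5": 20,
    "K6": 1.12215644112678,
    "K7": 2.08202182338753,
    "K8": 2.6663471063342,
    "K9": 0.164486503458945,
    "v1": 14.0998903119549,
    "v2": 0.1,
    "v3": 0.1,
    "v4": 4.22929443391627,
    "v5": 0.01,
    "v6": 2.6799106914425,
    "v7": 0.00376123770473302,
    "v8": 0.674995679210422,
    "ks": 1.72227857388353,
    "ksb": 0.1,
    "ktl1": 0.5,
    "ktl2": 0.745964762304427,
    "ktrs1": 0.2,
    "ktrs2": 0.2,
    "h": 2
  }
}
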