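{
  "name": "hypo_switch",
  "target": "fold_bistable_hypo",
  "seed": 1,
  "n_starts": 40,
  "verification": {
    "kind": "irreversible_bistable",
    "orientation": "hypo",
    "S1": 0.33651143900816,
    "S2": 0.00912390371019504,
    "basal": 0.1
  },
  "params": {
    "V_in": 1,
    "V_ex": 1,
    "V_nu": 1,
    "kdiff1": 0.108824111679265,
    "k1ex": 1,
    "k2in": 0.132666275382226,
    "k2ex": 0.05,
    "k3in": 0.2,
    "k3ex": 0.05,
    "d1": 0.05,
    "d2": 0.1,
    "d3": 0.05,
    "d4": 0.0476241199740748,
    "d5": 0.02,
    "d6": 0.01,
    "d7": 0.01,
    "d8": 0.02,
    "d9": 0.269784936516402,
    "d10": 0.05,
    "d11": 0.05,
    "d12": 0.05,
    "d13": 0.05,
    "d14": 0.1,
    "d15": 0.1,
    "kGRC": 5.84344352792231,
    "kGRdim": 5.68719340909983,
    "kCRC": 192.214227348049,
    "kGC2": 714.294907408917,
    "K1": 19.9639204480195,
    "K3": 17.5332479743611,
    "K4": 14.0904153274751,
    "K5": 20,
    "K6": 8.69998360996012,
    "K7": 26.0776413419272,
    "K8": 2.37964495452516,
    "K9": 3.35459876086654,
    "v1": 2.28362667503334,
    "v2": 0.1,
    "v3": 0.1,
    "v4": 0.87612911953475,
    "v5": 0.01,
    "v6": 1.95020112729194,
    "v7": 0.00532806683720893,
    "v8": 1.38213232048401,
    "ks": 5.72331288719775,
    "ksb": 0.1,
    "ktl1": 0.5,
    "ktl2": 0.223461012363752,
    "ktrs1": 0.2,
    "ktrs2": 0.2,
    "h": 2
  }
}
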