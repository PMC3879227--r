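{
  "name": "hyper_switch",
  "target": "fold_bistable_hyper",
  "seed": 1,
  "n_starts": 40,
  "verification": {
    "kind": "irreversible_bistable",
    "orientation": "hyper",
    "S1": 0.244686197457902,
    "S2": 0.0586162561123851,
    "basal": 0.1
  },
  "params": {
    "V_in": 1,
    "V_ex": 1,
    "V_nu": 1,
    "kdiff1": 1.40699906318436,
    "k1ex": 1,
    "k2in": 3.08710376330085,
    "k2ex": 0.00708756252158789,
    "k3in": 0.2,
    "k3ex": 0.05,
    "d1": 0.279250772870117,
    "d2": 0.531645503088572,
    "d3": 0.05,
    "d4": 0.0947298575272958,
    "d5": 0.02,
    "d6": 0.01,
    "d7": 0.01,
    "d8": 0.0173550435932199,
    "d9": 0.276700081659791,
    "d10": 0.05,
    "d11": 0.05,
    "d12": 0.05,
    "d13": 0.05,
    "d14": 0.1,
    "d15": 0.1,
    "kGRC": 10.9527977493041,
    "kGRdim": 3.22330927374771,
    "kCRC": 35.9038403290081,
    "kGC2": 3000,
    "K1": 46.9996834688497,
    "K3": 34.095310871374,
    "K4": 8.36913451120219,
    "K5": 20,
    "K6": 1.98267204549179,
    "K7": 0.577646274323566,
    "K8": 0.894732589943444,
    "K9": 0.16698129954976,
    "v1": 15.3004173716714,
    "v2": 0.1,
    "v3": 0.1,
    "v4": 4.20233495486473,
    "v5": 0.01,
    "v6": 5.3255148869221,
    "v7": 0.00133196581158115,
    "v8": 0.528534295029785,
    "ks": 6.44509320448677,
    "ksb": 0.1,
    "ktl1": 0.5,
    "ktl2": 0.598544711071128,
    "ktrs1": 0.2,
    "ktrs2": 0.2,
    "h": 2
  }
}
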