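{
  "d": 0.08,
  "delta": 0.027,
  "lam": 0.2,
  "b_mean": 8,
  "mu0": 4,
  "cv_tr": 0.4
}
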