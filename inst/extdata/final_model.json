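{
  "name": "final",
  "version": "1.0",
  "tvcl": 3.79,
  "theta_crrt": 0.44,
  "tvv1": 2.4,
  "tvv2": 8.56,
  "tvq": 21.3,
  "cv_cl": 47.1,
  "cv_v2": 44,
  "cv_ruv": 47.3
}
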