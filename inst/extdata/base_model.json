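{
  "name": "base",
  "version": "1.0",
  "tvcl": 2.65,
  "tvv1": 2.53,
  "tvv2": 9.61,
  "tvq": 20.8,
  "cv_cl": 69.4,
  "cv_v2": 61,
  "cv_ruv": 49.7
}
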