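{
  "seed": 1,
  "outDir": ".",
  "volumes": "/tmp/RtmpyxHARR/nonec08438766b4",
  "vector": "inv",
  "levels": 64,
  "out": "features.csv",
  "help": false
}
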