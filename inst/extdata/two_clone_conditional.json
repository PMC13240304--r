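{
  "schema_version": 1,
  "clones": [
    {"id": "AML1", "fraction": 0.5, "x": 0.9, "y": 0.5, "z": 0.6},
    {"id": "AML2", "fraction": 0.5, "x": 0.8, "y": 0.7, "z": 0.7}
  ],
  "default_drug": {"d": 0.5, "alpha": 1}
}
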