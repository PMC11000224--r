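{
  "nodes": [
    {
      "id": "root",
      "layer": 1,
      "atoms": "1-6",
      "calculator": "ff"
    },
    {
      "id": "bridge",
      "layer": 2,
      "atoms": "2-5",
      "calculator": "sqm"
    }
  ]
}
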