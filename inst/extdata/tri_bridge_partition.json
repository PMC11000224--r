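{
  "nodes": [
    {
      "id": "root",
      "layer": 1,
      "atoms": "1-40",
      "calculator": "ff"
    },
    {
      "id": "mid1",
      "layer": 2,
      "atoms": "5-12",
      "calculator": "sqm"
    },
    {
      "id": "mid2",
      "layer": 2,
      "atoms": "17-24",
      "calculator": "sqm"
    },
    {
      "id": "mid3",
      "layer": 2,
      "atoms": "29-36",
      "calculator": "sqm"
    },
    {
      "id": "core1",
      "layer": 3,
      "atoms": "8-9",
      "calculator": "dft"
    },
    {
      "id": "core2",
      "layer": 3,
      "atoms": "20-21",
      "calculator": "dft"
    },
    {
      "id": "core3",
      "layer": 3,
      "atoms": "32-33",
      "calculator": "dft"
    }
  ]
}
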