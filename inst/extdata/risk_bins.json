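{
  "age_threshold": 55,
  "size_breaks": [5, 10, 15],
  "mitoses_upper": 2,
  "ki67_breaks": [1, 10],
  "necrosis_threshold": 10,
  "categories": {
    "three_variable": {"low_max": 2, "intermediate_max": 4},
    "four_variable": {"low_max": 3, "intermediate_max": 5}
  }
}
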