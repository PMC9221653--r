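{
  "10x10": {"diameter_mm": 10, "length_mm": 10, "magnetisation_kA_per_m": 1150},
  "5x10":  {"diameter_mm": 10, "length_mm": 5,  "magnetisation_kA_per_m": 1150},
  "3x10":  {"diameter_mm": 10, "length_mm": 3,  "magnetisation_kA_per_m": 1150}
}
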