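[
  {"label": "S1", "x_mm": -111.7, "y_mm": 1.1,  "z_mm": 172.2},
  {"label": "S2", "x_mm": -11.1,  "y_mm": 13.8, "z_mm": 172.1},
  {"label": "S3", "x_mm": -10.9,  "y_mm": 29.8, "z_mm": 171.5},
  {"label": "S4", "x_mm": -10.1,  "y_mm": 1.0,  "z_mm": 174.0},
  {"label": "S5", "x_mm": -10.1,  "y_mm": 15.6, "z_mm": 174.1},
  {"label": "S6", "x_mm": -100.0, "y_mm": 33.5, "z_mm": 173.4}
]
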