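{
  "zpg": {
    "drive_conversion_female": 0.99,
    "drive_conversion_male": 0.96,
    "germline_resistance_female": 0.01,
    "germline_resistance_male": 0.02,
    "embryo_resistance_maternal": 0.08,
    "paternal_deposition": 0.69,
    "somatic_cost_female": 0.3,
    "somatic_cost_male": 0,
    "x_shredding": 0
  },
  "zpg2": {
    "drive_conversion_female": 0.99,
    "drive_conversion_male": 0.96,
    "germline_resistance_female": 0.01,
    "germline_resistance_male": 0.02,
    "embryo_resistance_maternal": 0.08,
    "paternal_deposition": 0,
    "somatic_cost_female": 0.5,
    "somatic_cost_male": 0,
    "x_shredding": 0
  },
  "zpgX": {
    "drive_conversion_female": 0.99,
    "drive_conversion_male": 0.96,
    "germline_resistance_female": 0.01,
    "germline_resistance_male": 0.02,
    "embryo_resistance_maternal": 0.08,
    "paternal_deposition": 0.69,
    "somatic_cost_female": 0.3,
    "somatic_cost_male": 0,
    "x_shredding": 0.93
  },
  "zpg2X": {
    "drive_conversion_female": 0.99,
    "drive_conversion_male": 0.96,
    "germline_resistance_female": 0.01,
    "germline_resistance_male": 0.02,
    "embryo_resistance_maternal": 0.08,
    "paternal_deposition": 0,
    "somatic_cost_female": 0.5,
    "somatic_cost_male": 0,
    "x_shredding": 0.93
  },
  "nos": {
    "drive_conversion_female": 0.99,
    "drive_conversion_male": 0.98,
    "germline_resistance_female": 0.01,
    "germline_resistance_male": 0.01,
    "embryo_resistance_maternal": 0.14,
    "paternal_deposition": 0,
    "somatic_cost_female": 0.45,
    "somatic_cost_male": 0.45,
    "x_shredding": 0
  },
  "nosF": {
    "drive_conversion_female": 0.99,
    "drive_conversion_male": 0.98,
    "germline_resistance_female": 0.01,
    "germline_resistance_male": 0.01,
    "embryo_resistance_maternal": 0.14,
    "paternal_deposition": 0,
    "somatic_cost_female": 0.45,
    "somatic_cost_male": 0,
    "x_shredding": 0
  },
  "nosF2": {
    "drive_conversion_female": 0.99,
    "drive_conversion_male": 0.98,
    "germline_resistance_female": 0.01,
    "germline_resistance_male": 0.01,
    "embryo_resistance_maternal": 0.14,
    "paternal_deposition": 0,
    "somatic_cost_female": 0.15,
    "somatic_cost_male": 0,
    "x_shredding": 0
  },
  "nosF3": {
    "drive_conversion_female": 0.99,
    "drive_conversion_male": 0.98,
    "germline_resistance_female": 0.01,
    "germline_resistance_male": 0.01,
    "embryo_resistance_maternal": 0.14,
    "paternal_deposition": 0,
    "somatic_cost_female": 0,
    "somatic_cost_male": 0,
    "x_shredding": 0
  },
  "wildtype": {
    "drive_conversion_female": 0,
    "drive_conversion_male": 0,
    "germline_resistance_female": 0,
    "germline_resistance_male": 0,
    "embryo_resistance_maternal": 0,
    "paternal_deposition": 0,
    "somatic_cost_female": 0,
    "somatic_cost_male": 0,
    "x_shredding": 0
  }
}
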