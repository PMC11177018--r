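{
  "scanners": {
    "SSE": {
      "name": "SSE",
      "n_male": 15,
      "n_female": 13,
      "mas_mean": 205.04,
      "mas_sd": 55.65,
      "mas_range": [20, 345],
      "kvp": 110,
      "scan_length_mean": 13.18,
      "scan_length_sd": 1.6,
      "scan_length_range": [8.38, 17.980000001],
      "pitch": 1,
      "scan_mode": "axial",
      "rotation_time_s": 1,
      "beam_width_mm": 10
    },
    "PI": {
      "name": "PI",
      "n_male": 12,
      "n_female": 15,
      "mas_mean": 188.39,
      "mas_sd": 4.86,
      "mas_range": [10, 250],
      "kvp": 120,
      "scan_length_mean": 15.8,
      "scan_length_sd": 1.7,
      "scan_length_range": [10.7, 20.900000001],
      "pitch": 0.563,
      "scan_mode": "helical",
      "rotation_time_s": 0.5,
      "beam_width_mm": 10
    },
    "TA": {
      "name": "TA",
      "n_male": 11,
      "n_female": 8,
      "mas_mean": 160,
      "mas_sd": 0,
      "mas_range": [15, 450],
      "kvp": 120,
      "scan_length_mean": 14.24,
      "scan_length_sd": 0.98,
      "scan_length_range": [11.3, 17.180000001],
      "pitch": 1,
      "scan_mode": "helical",
      "rotation_time_s": 1.5,
      "beam_width_mm": 9.6
    }
  },
  "ages": {
    "male": {
      "mean": 43,
      "sd": 19,
      "range": [18, 78]
    },
    "female": {
      "mean": 46,
      "sd": 17,
      "range": [18, 79]
    }
  }
}
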