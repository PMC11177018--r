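{
  "description": "Printed group means of the reference adult head-CT survey (three-scanner multicentre service, 38 male / 36 female records) used as calibration targets and report anchors. Units in key names.",
  "by_sex": {
    "female": {
      "ctdivol_mGy": 44.84,
      "dlp_mGycm": 635.4,
      "thyroid_dose_mGy": 2.66,
      "effective_dose_mSv": 1.6,
      "lar_per_100k": 0.91
    },
    "male": {
      "ctdivol_mGy": 42.69,
      "dlp_mGycm": 644.6,
      "thyroid_dose_mGy": 2.52,
      "effective_dose_mSv": 1.5,
      "lar_per_100k": 0.2
    }
  },
  "by_mode": {
    "female": {"helical": 3.1, "axial": 1.87},
    "male": {"helical": 3.23, "axial": 1.45}
  },
  "counts": {
    "female_helical": 23, "female_axial": 13,
    "male_helical": 23, "male_axial": 15
  }
}
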