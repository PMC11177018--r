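{
  "profiles": {
    "SSE": {
      "name": "SSE",
      "ctdiw_ref": 16.9500705692941,
      "kvp_ref": 120,
      "kvp_exponent": 2,
      "beam_width_mm": 10,
      "supported_kvp": [80, 110, 130],
      "modes": ["axial", "helical"],
      "mas_range": [20, 345]
    },
    "PI": {
      "name": "PI",
      "ctdiw_ref": 18.1778472132672,
      "kvp_ref": 120,
      "kvp_exponent": 2,
      "beam_width_mm": 10,
      "supported_kvp": [100, 120, 140],
      "modes": "helical",
      "mas_range": [10, 250]
    },
    "TA": {
      "name": "TA",
      "ctdiw_ref": 25.6338313259263,
      "kvp_ref": 120,
      "kvp_exponent": 2,
      "beam_width_mm": 9.6,
      "supported_kvp": [100, 120, 135],
      "modes": "helical",
      "mas_range": [15, 450]
    }
  },
  "scatter": {
    "A": 0.320564818943752,
    "mu": 0.175721334637032
  },
  "geometry": {
    "male": {
      "neck_cm": 9,
      "thyroid_extent_cm": 4,
      "thyroid_offset_cm": 2.99090738307759
    },
    "female": {
      "neck_cm": 8,
      "thyroid_extent_cm": 4,
      "thyroid_offset_cm": 3.99088353521332
    }
  },
  "distributed_factor": 0.0434688274705633,
  "k_head": 0.0021,
  "overrange_mult": 0.5,
  "fit": {
    "rms": 0.00276739138755269,
    "residuals": {
      "ctdivol_f": 0.00356589379640941,
      "ctdivol_m": -0.00359085212699053,
      "thyroid_f": 0.000873462623392959,
      "thyroid_m": -0.000276186580713602,
      "ed_f": -0.00417585789812783,
      "ed_m": 0.00414167863132834,
      "thyroid_hel": -0.000454428214643527,
      "thyroid_ax": -0.000144260581482157
    },
    "targets": {
      "ctdivol_f": 44.84,
      "ctdivol_m": 42.69,
      "thyroid_f": 2.66,
      "thyroid_m": 2.52,
      "ed_f": 1.6,
      "ed_m": 1.5,
      "thyroid_hel": 3.165,
      "thyroid_ax": 1.645
    },
    "achieved": {
      "ctdivol_f": 44.999894677831,
      "ctdivol_m": 42.5367065226988,
      "thyroid_f": 2.66232341057823,
      "thyroid_m": 2.5193040098166,
      "ed_f": 1.593318627363,
      "ed_m": 1.50621251794699,
      "thyroid_hel": 3.16356173470065,
      "thyroid_ax": 1.64476269134346
    },
    "convergence": 0,
    "n": 7400,
    "seed": 20240112
  }
}
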