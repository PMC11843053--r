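[
  {
    "site_id": "siteA",
    "n_patients": 50,
    "intensity_offset": 0,
    "noise_sd": 4,
    "tumor_radius_range": [4, 9],
    "lung_ellipse_params": [24, 17],
    "grid": [64, 64],
    "seed": 101
  },
  {
    "site_id": "siteB",
    "n_patients": 50,
    "intensity_offset": 18,
    "noise_sd": 6,
    "tumor_radius_range": [5, 10],
    "lung_ellipse_params": [22, 16],
    "grid": [64, 64],
    "seed": 202
  },
  {
    "site_id": "siteC",
    "n_patients": 50,
    "intensity_offset": -12,
    "noise_sd": 8,
    "tumor_radius_range": [4, 8],
    "lung_ellipse_params": [25, 18],
    "grid": [64, 64],
    "seed": 303
  }
]
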