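[
  {"meal": "NPM", "algorithm": "CC", "mean_dose_u": 6.97, "sd_u": 0.61},
  {"meal": "NPM", "algorithm": "FPU", "mean_dose_u": 8.70, "sd_u": 0.69},
  {"meal": "HPFM", "algorithm": "CC", "mean_dose_u": 4.92, "sd_u": 0.54},
  {"meal": "HPFM", "algorithm": "FPU", "mean_dose_u": 7.23, "sd_u": 0.68}
]
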