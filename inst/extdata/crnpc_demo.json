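{
  "seed": 42,
  "phantom": {
    "architecture": "crnpc",
    "voxel_size": 4,
    "box_nm": 128,
    "resolution_nm": 6,
    "snr": 1,
    "wedge": { "tilt_min": -60, "tilt_max": 60 }
  },
  "fit": {
    "angular_step": 30,
    "translation_step": 1,
    "alpha": 0.05,
    "lowpass_nm": 8
  },
  "analyze": { "enabled": true },
  "coexpr": {
    "enabled": true,
    "n_genes": 400,
    "n_samples": 500,
    "within_module_corr": 0.8,
    "modules": { "npc": 20, "coat": 20 },
    "p_threshold": 0.01
  }
}
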