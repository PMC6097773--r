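{
  "comment": "Default ground-truth fixture: 10-region visual spatial attention network, time-varying MVAR connection schedule, AR(10) visual-input process, and the MNI-to-spherical-head affine. All onsets/durations in ms relative to stimulus onset (end of the 200 ms baseline).",
  "params": {
    "fs": 256,
    "duration_ms": 1200,
    "baseline_ms": 200,
    "source_snr": 20,
    "tv_duration_ms": 200,
    "tv_peak_amplitude": 0.35,
    "baseline_strength": 0.2,
    "interhemispheric_strength": 0.5
  },
  "regions": [
    {"name": "V1",    "label": "Primary visual cortex (V1)",                          "mni_xyz": [6.3, -82.3, -3.7], "hemisphere": "right"},
    {"name": "VA_R",  "label": "Right visual area (R VA)",                            "mni_xyz": [15, -71, 5],       "hemisphere": "right"},
    {"name": "IPS_R", "label": "Right intraparietal sulcus (IPS R)",                  "mni_xyz": [42, -42, 48],      "hemisphere": "right"},
    {"name": "FEF_R", "label": "Right frontal eye fields (FEF R)",                    "mni_xyz": [38, -6, 56],       "hemisphere": "right"},
    {"name": "TPJ_R", "label": "Right temporoparietal junction (TPJ R)",              "mni_xyz": [66, -48, 20],      "hemisphere": "right"},
    {"name": "VFC_R", "label": "Right ventral frontal cortex/anterior insula (VFC/AI R)", "mni_xyz": [39, 0, 39],    "hemisphere": "right"},
    {"name": "MFG_R", "label": "Right middle frontal gyrus (MFG R)",                  "mni_xyz": [47, 38, 29],       "hemisphere": "right"},
    {"name": "VA_L",  "label": "Left visual area (VA L)",                             "mni_xyz": [-14, -81, 9],      "hemisphere": "left"},
    {"name": "IPS_L", "label": "Left intraparietal sulcus (IPS L)",                   "mni_xyz": [-44, -57, 48],     "hemisphere": "left"},
    {"name": "FEF_L", "label": "Left frontal eye fields (FEF L)",                     "mni_xyz": [-43, -7, 52],      "hemisphere": "left"}
  ],
  "connections": [
    {"sender": "V1",    "receiver": "VA_L",  "lag_ms": 4,  "category": "input",            "tv": {"onset_ms": 100, "duration_ms": 200, "peak_amplitude": 0.35}},
    {"sender": "V1",    "receiver": "VA_R",  "lag_ms": 4,  "category": "input",            "tv": {"onset_ms": 100, "duration_ms": 200, "peak_amplitude": 0.35}},
    {"sender": "VA_L",  "receiver": "VA_R",  "lag_ms": 16, "category": "interhemispheric", "tv": null},
    {"sender": "VA_R",  "receiver": "VA_L",  "lag_ms": 16, "category": "interhemispheric", "tv": null},
    {"sender": "IPS_L", "receiver": "IPS_R", "lag_ms": 16, "category": "interhemispheric", "tv": null},
    {"sender": "IPS_R", "receiver": "IPS_L", "lag_ms": 16, "category": "interhemispheric", "tv": null},
    {"sender": "FEF_L", "receiver": "FEF_R", "lag_ms": 16, "category": "interhemispheric", "tv": null},
    {"sender": "FEF_R", "receiver": "FEF_L", "lag_ms": 16, "category": "interhemispheric", "tv": null},
    {"sender": "IPS_L", "receiver": "VA_L",  "lag_ms": 16, "category": "top_down",         "tv": {"onset_ms": 300, "duration_ms": 200, "peak_amplitude": 0.35}},
    {"sender": "IPS_R", "receiver": "VA_R",  "lag_ms": 16, "category": "top_down",         "tv": {"onset_ms": 300, "duration_ms": 200, "peak_amplitude": 0.35}},
    {"sender": "FEF_L", "receiver": "IPS_L", "lag_ms": 16, "category": "top_down",         "tv": {"onset_ms": 300, "duration_ms": 200, "peak_amplitude": 0.35}},
    {"sender": "FEF_R", "receiver": "IPS_R", "lag_ms": 16, "category": "top_down",         "tv": {"onset_ms": 300, "duration_ms": 200, "peak_amplitude": 0.35}},
    {"sender": "IPS_L", "receiver": "FEF_L", "lag_ms": 16, "category": "top_down",         "tv": {"onset_ms": 500, "duration_ms": 200, "peak_amplitude": 0.35}},
    {"sender": "IPS_R", "receiver": "FEF_R", "lag_ms": 16, "category": "top_down",         "tv": {"onset_ms": 500, "duration_ms": 200, "peak_amplitude": 0.35}},
    {"sender": "MFG_R", "receiver": "FEF_R", "lag_ms": 16, "category": "top_down",         "tv": {"onset_ms": 300, "duration_ms": 200, "peak_amplitude": 0.35}},
    {"sender": "MFG_R", "receiver": "TPJ_R", "lag_ms": 16, "category": "top_down",         "tv": {"onset_ms": 300, "duration_ms": 200, "peak_amplitude": 0.35}},
    {"sender": "VA_R",  "receiver": "TPJ_R", "lag_ms": 16, "category": "stimulus_driven",  "tv": {"onset_ms": 100, "duration_ms": 200, "peak_amplitude": 0.35}},
    {"sender": "VA_L",  "receiver": "TPJ_R", "lag_ms": 16, "category": "stimulus_driven",  "tv": {"onset_ms": 100, "duration_ms": 200, "peak_amplitude": 0.35}},
    {"sender": "TPJ_R", "receiver": "VFC_R", "lag_ms": 16, "category": "stimulus_driven",  "tv": {"onset_ms": 100, "duration_ms": 200, "peak_amplitude": 0.35}},
    {"sender": "VFC_R", "receiver": "TPJ_R", "lag_ms": 16, "category": "stimulus_driven",  "tv": {"onset_ms": 300, "duration_ms": 200, "peak_amplitude": 0.35}},
    {"sender": "TPJ_R", "receiver": "IPS_R", "lag_ms": 16, "category": "stimulus_driven",  "tv": {"onset_ms": 100, "duration_ms": 200, "peak_amplitude": 0.35}},
    {"sender": "FEF_R", "receiver": "MFG_R", "lag_ms": 16, "category": "stimulus_driven",  "tv": {"onset_ms": 100, "duration_ms": 200, "peak_amplitude": 0.35}},
    {"sender": "TPJ_R", "receiver": "MFG_R", "lag_ms": 16, "category": "stimulus_driven",  "tv": {"onset_ms": 100, "duration_ms": 200, "peak_amplitude": 0.35}}
  ],
  "input_ar": {
    "comment": "Synthetic AR(10) standing in for the real-EEG-derived visual input: five complex pole pairs (freq Hz, modulus) giving 1/f decay plus an alpha resonance. phi[k] multiplies y[n-k].",
    "poles": [[0.7, 0.95], [10, 0.97], [25, 0.8], [45, 0.75], [80, 0.7]],
    "phi": [5.228376114438044, -12.402145088709219, 18.067029172307222, -18.708929207633012, 15.276915820234894, -10.553776425682791, 6.224906126775736, -2.919566915535134, 0.936884618972567, -0.1497922209],
    "fs": 256
  },
  "mni_affine": {
    "comment": "Synthetic similarity map from MNI mm into the spherical brain shell: x_head = scale * (x_mni - center). Fitted so mapped seeds lie inside the default 80 mm brain shell near the source-shell radius.",
    "center": [15.23, -35.63, 30.23],
    "scale": 0.947617
  }
}
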