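{
  "package_version": "0.1.0",
  "config_hash": "30c974c6",
  "config": {
    "seed": 21,
    "condition": {
      "treatment": "ctrl",
      "div": 14
    },
    "study": {
      "n_experiments": 2,
      "devices_treated": 2,
      "devices_control": 2,
      "presyn_somas": 40,
      "postsyn_somas": 40
    },
    "qc": {
      "min_somas": 40,
      "min_fields": 4,
      "min_axons": 10,
      "min_dendrite_um": 650
    },
    "tes": {
      "epsilon": 0.05
    },
    "rate": {
      "spike_nM": 500,
      "n_axons": 100,
      "window_days": 2
    },
    "output_dir": "pipeline_out"
  },
  "n_devices": 8,
  "n_excluded": 0,
  "exclusions": [],
  "tes": [
    {
      "experiment_id": "E01",
      "condition": "ctrl",
      "div": 14,
      "pair": "presyn_postsyn",
      "target_excess": 0,
      "source_mean_excess": 1,
      "tes": 0
    },
    {
      "experiment_id": "E02",
      "condition": "ctrl",
      "div": 14,
      "pair": "presyn_postsyn",
      "target_excess": 0,
      "source_mean_excess": 1,
      "tes": 0
    }
  ],
  "tes_summary": {},
  "rate": {},
  "assumptions": {}
}
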