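{
  "n_pos": 56,
  "n_neg": 53,
  "n_total": 109,
  "panels": {
    "ca125": {
      "cop": 248.55,
      "sens_pct": 73.2, "spec_pct": 73.6, "acc_pct": 73.3,
      "ppv_pct": 74.5, "npv_pct": 72.2,
      "auc_pct": 76.7, "ci_lo_pct": 67.8, "ci_hi_pct": 85.6, "correct_n": 84,
      "suboptimal": {"mean": 1157.62, "sd": 2105.195, "median": 600.00, "min": 4.29, "max": 9934.00},
      "optimal": {"mean": 237.52, "sd": 319.431, "median": 120.30, "min": 5.10, "max": 1941.90}
    },
    "fasn": {
      "cop": 0.445,
      "sens_pct": 62.5, "spec_pct": 60.4, "acc_pct": 61.4,
      "ppv_pct": 62.5, "npv_pct": 60.4,
      "auc_pct": 65.3, "ci_lo_pct": 54.8, "ci_hi_pct": 75.8, "correct_n": 71,
      "suboptimal": {"mean": 0.58, "sd": 0.271, "median": 0.50, "min": 0.11, "max": 1.59},
      "optimal": {"mean": 0.46, "sd": 0.288, "median": 0.37, "min": 0.03, "max": 1.19}
    },
    "gls": {
      "cop": 22.895,
      "sens_pct": 73.2, "spec_pct": 75.5, "acc_pct": 74.3,
      "ppv_pct": 75.9, "npv_pct": 72.7,
      "auc_pct": 74.1, "ci_lo_pct": 64.6, "ci_hi_pct": 83.7, "correct_n": 81,
      "suboptimal": {"mean": 25.19, "sd": 5.415, "median": 25.25, "min": 14.27, "max": 37.50},
      "optimal": {"mean": 20.83, "sd": 5.562, "median": 20.08, "min": 10.81, "max": 38.01}
    },
    "ca125_fasn": {
      "cop": 0.69,
      "sens_pct": 71.4, "spec_pct": 71.7, "acc_pct": 71.6,
      "ppv_pct": 72.7, "npv_pct": 70.4,
      "auc_pct": 76.9, "ci_lo_pct": 68.1, "ci_hi_pct": 85.8, "correct_n": 84,
      "suboptimal": {"mean": 1.02, "sd": 0.581, "median": 0.93, "min": 0.21, "max": 3.18},
      "optimal": {"mean": 0.55, "sd": 0.314, "median": 0.49, "min": 0.03, "max": 1.58}
    },
    "ca125_gls": {
      "cop": 29.16,
      "sens_pct": 82.1, "spec_pct": 73.6, "acc_pct": 77.9,
      "ppv_pct": 76.6, "npv_pct": 79.6,
      "auc_pct": 85.4, "ci_lo_pct": 78.4, "ci_hi_pct": 92.3, "correct_n": 91,
      "suboptimal": {"mean": 42.93, "sd": 12.913, "median": 44.99, "min": 17.15, "max": 75.00},
      "optimal": {"mean": 25.83, "sd": 9.807, "median": 22.47, "min": 10.81, "max": 53.52}
    },
    "ca125_fasn_gls": {
      "cop": 0.83,
      "sens_pct": 87.5, "spec_pct": 73.6, "acc_pct": 80.7,
      "ppv_pct": 77.8, "npv_pct": 84.8,
      "auc_pct": 87.7, "ci_lo_pct": 81.0, "ci_hi_pct": 94.4, "correct_n": 96,
      "suboptimal": {"mean": 1.70, "sd": 0.967, "median": 1.48, "min": 0.22, "max": 4.68},
      "optimal": {"mean": 0.66, "sd": 0.388, "median": 0.66, "min": 0.03, "max": 2.16}
    }
  }
}
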