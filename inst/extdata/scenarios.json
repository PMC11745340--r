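{
  "paper_default": {
    "description": "8-h night; realized N2 density ~11 events/min, refractory ~1.8 s, history peak ~1.9 at 3.5 s, preferred phase 0 in N2 shifting to -pi/8 in N3",
    "duration_s": 28800,
    "epoch_s": 30,
    "so_freq_hz": 0.85,
    "dwell": 0.9,
    "stationary": {"N1": 0.06, "N2": 0.48, "N3": 0.24, "REM": 0.16, "Wake": 0.06},
    "stage_log_rates": {"N1": -3.441170, "N2": -1.638017, "N3": -2.497466, "REM": -4.787492, "Wake": -5.703782},
    "phase_beta": [0.22, 0.0],
    "stage_phase_beta": {
      "N1": [0.0, 0.0],
      "N2": [0.0, 0.0],
      "N3": [-0.016746, -0.084190],
      "REM": [0.0, 0.0],
      "Wake": [0.0, 0.0]
    },
    "sop_alpha": null,
    "sop_phase_beta": null,
    "intercept": null,
    "history_knots": [0, 0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4, 5, 6.5, 8, 10, 12.5, 15],
    "history_coeffs": [-4.6, -4.2, -3.0, -0.9, 0.28, 0.46, 0.55, 0.642, 0.55, 0.12, -0.01, 0, 0, 0, 0],
    "history_mode": "last",
    "sop_profile": {"N1": 0.35, "N2": 0.65, "N3": 0.95, "REM": 0.3, "Wake": 0.05},
    "spec": "stage+phase+interaction+history15",
    "seed": 101
  },
  "null_history": {
    "description": "paper_default with all history coefficients set to 0",
    "duration_s": 28800,
    "epoch_s": 30,
    "so_freq_hz": 0.85,
    "dwell": 0.9,
    "stationary": {"N1": 0.06, "N2": 0.48, "N3": 0.24, "REM": 0.16, "Wake": 0.06},
    "stage_log_rates": {"N1": -3.401197, "N2": -1.697116, "N3": -2.484907, "REM": -4.787492, "Wake": -5.703782},
    "phase_beta": [0.22, 0.0],
    "stage_phase_beta": {
      "N1": [0.0, 0.0],
      "N2": [0.0, 0.0],
      "N3": [-0.016746, -0.084190],
      "REM": [0.0, 0.0],
      "Wake": [0.0, 0.0]
    },
    "sop_alpha": null,
    "sop_phase_beta": null,
    "intercept": null,
    "history_knots": [0, 0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4, 5, 6.5, 8, 10, 12.5, 15],
    "history_coeffs": [0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0],
    "history_mode": "last",
    "sop_profile": {"N1": 0.35, "N2": 0.65, "N3": 0.95, "REM": 0.3, "Wake": 0.05},
    "spec": "stage+phase+interaction",
    "seed": 102
  },
  "phase_shift": {
    "description": "history-free night with stronger coupling (M = 0.35); preferred phase 0 in N2, -pi/8 in N3",
    "duration_s": 28800,
    "epoch_s": 30,
    "so_freq_hz": 0.85,
    "dwell": 0.9,
    "stationary": {"N1": 0.06, "N2": 0.48, "N3": 0.24, "REM": 0.16, "Wake": 0.06},
    "stage_log_rates": {"N1": -3.401197, "N2": -1.697116, "N3": -2.484907, "REM": -4.787492, "Wake": -5.703782},
    "phase_beta": [0.35, 0.0],
    "stage_phase_beta": {
      "N1": [0.0, 0.0],
      "N2": [0.0, 0.0],
      "N3": [-0.026642, -0.133939],
      "REM": [0.0, 0.0],
      "Wake": [0.0, 0.0]
    },
    "sop_alpha": null,
    "sop_phase_beta": null,
    "intercept": null,
    "history_knots": [0, 0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4, 5, 6.5, 8, 10, 12.5, 15],
    "history_coeffs": [0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0],
    "history_mode": "last",
    "sop_profile": {"N1": 0.35, "N2": 0.65, "N3": 0.95, "REM": 0.3, "Wake": 0.05},
    "spec": "stage+phase+interaction",
    "seed": 103
  },
  "history_only": {
    "description": "equal baseline rates in every stage (realized ~8 events/min), no phase coupling, paper-like history structure",
    "duration_s": 28800,
    "epoch_s": 30,
    "so_freq_hz": 0.85,
    "dwell": 0.9,
    "stationary": {"N1": 0.06, "N2": 0.48, "N3": 0.24, "REM": 0.16, "Wake": 0.06},
    "stage_log_rates": {"N1": -1.989294, "N2": -1.989294, "N3": -1.989294, "REM": -1.989294, "Wake": -1.989294},
    "phase_beta": [0.0, 0.0],
    "stage_phase_beta": {
      "N1": [0.0, 0.0],
      "N2": [0.0, 0.0],
      "N3": [0.0, 0.0],
      "REM": [0.0, 0.0],
      "Wake": [0.0, 0.0]
    },
    "sop_alpha": null,
    "sop_phase_beta": null,
    "intercept": null,
    "history_knots": [0, 0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4, 5, 6.5, 8, 10, 12.5, 15],
    "history_coeffs": [-4.6, -4.2, -3.0, -0.9, 0.28, 0.46, 0.55, 0.642, 0.55, 0.12, -0.01, 0, 0, 0, 0],
    "history_mode": "last",
    "sop_profile": {"N1": 0.35, "N2": 0.65, "N3": 0.95, "REM": 0.3, "Wake": 0.05},
    "spec": "stage+phase+interaction+history15",
    "seed": 104
  },
  "phase_depth": {
    "description": "SOP sweeps 0..1 over the night; preferred phase drifts from 0 (SOP 0) to -pi/8 (SOP 1); quadratic SOP rate term",
    "duration_s": 28800,
    "epoch_s": 30,
    "so_freq_hz": 0.85,
    "dwell": 0.9,
    "stationary": {"N1": 0.06, "N2": 0.48, "N3": 0.24, "REM": 0.16, "Wake": 0.06},
    "stage_log_rates": null,
    "phase_beta": [0.22, 0.0],
    "stage_phase_beta": {
      "N1": [0.0, 0.0],
      "N2": [0.0, 0.0],
      "N3": [0.0, 0.0],
      "REM": [0.0, 0.0],
      "Wake": [0.0, 0.0]
    },
    "sop_alpha": [0.8, -0.3],
    "sop_phase_beta": [-0.016746, -0.084190],
    "intercept": -2.302585,
    "history_knots": [0, 0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4, 5, 6.5, 8, 10, 12.5, 15],
    "history_coeffs": [0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0],
    "history_mode": "last",
    "sop_profile": "sweep",
    "spec": "sop+phase+sopphase",
    "seed": 105
  }
}
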