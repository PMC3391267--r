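{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "patternsplit pipeline configuration",
  "description": "All keys are optional; omitted keys take the package defaults (see ?default_config). Unknown keys are rejected by the validator.",
  "type": "object",
  "additionalProperties": false,
  "properties": {
    "master_seed": {"type": "integer", "description": "master seed; all child seeds derive from it"},
    "n_subjects": {"type": "integer", "minimum": 2, "default": 13},
    "n_runs": {"type": "integer", "minimum": 2, "default": 10},
    "scenario": {"enum": ["holistic", "parts_based", "both", "null"]},
    "output_dir": {"type": "string"},
    "level": {"enum": ["bold", "amplitude"],
              "description": "full BOLD simulation + GLM, or trial-amplitude shortcut"},
    "design": {
      "type": "object", "additionalProperties": false,
      "properties": {
        "n_veridical": {"type": "integer", "default": 36},
        "n_scrambled": {"type": "integer", "default": 36},
        "trial_duration_s": {"type": "number", "default": 4},
        "n_fixation": {"type": "integer", "default": 12},
        "fixation_duration_s": {"type": "number", "default": 2},
        "lead_in_s": {"type": "number", "default": 8},
        "lead_out_s": {"type": "number", "default": 8},
        "tr_s": {"type": "number", "default": 2}
      }
    },
    "localizer": {
      "type": "object", "additionalProperties": false,
      "properties": {"n_runs": {"type": "integer", "default": 2}}
    },
    "behavior": {
      "type": "object", "additionalProperties": false,
      "properties": {
        "p_correct": {"type": "object", "description": "per-condition P(correct); defaults veridical 0.847, scrambled 0.727"},
        "p_no_response": {"type": "number", "default": 0.001},
        "rt_shift_s": {"type": "number", "default": 0.3},
        "rt_meanlog": {"type": "object"},
        "rt_sdlog": {"type": "number", "default": 0.25}
      }
    },
    "geometry": {
      "type": "object", "additionalProperties": false,
      "properties": {
        "dim": {"type": "array", "items": {"type": "integer"}},
        "voxel_size_mm": {"type": "array", "items": {"type": "number"}},
        "rois": {"type": "object",
                 "description": "name -> {center: [x,y,z], n_voxels}"}
      }
    },
    "ground_truth": {
      "type": "object", "additionalProperties": false,
      "properties": {
        "stability_base": {"type": "number", "default": 0},
        "stability_effect": {"type": "number", "default": 0.7},
        "pattern_mean": {"type": "object"},
        "pattern_sd": {"type": "number", "default": 1},
        "trial_noise_sd": {"type": "number", "default": 1},
        "localizer_amplitude": {"type": "object"}
      }
    },
    "noise": {
      "type": "object", "additionalProperties": false,
      "properties": {
        "sigma_thermal": {"type": "number", "default": 6},
        "ar1_coef": {"type": "number", "exclusiveMinimum": -1, "exclusiveMaximum": 1},
        "drift_amp": {"type": "number", "default": 2},
        "baseline": {"type": "number", "default": 100}
      }
    },
    "hrf": {
      "type": "object", "additionalProperties": false,
      "properties": {
        "delta_s": {"type": "number", "default": 2.25},
        "tau_s": {"type": "number", "default": 1.25},
        "alpha": {"type": "number", "default": 2}
      }
    },
    "analysis": {
      "type": "object", "additionalProperties": false,
      "properties": {
        "drift_order": {"type": "integer", "default": 1},
        "define_rois": {"type": "boolean", "default": false,
                        "description": "define ROIs from simulated localizer runs instead of using ground-truth masks"},
        "p_threshold": {"type": "number", "default": 0.01},
        "min_size": {"type": "integer", "default": 5},
        "connectivity": {"enum": [6, 26], "default": 26},
        "localizer_fwhm_mm": {"type": "number", "default": 5},
        "centering": {"type": "boolean", "default": true},
        "fisher_z": {"type": "boolean", "default": false},
        "match_counts": {"type": "boolean", "default": true},
        "alpha": {"type": "number", "default": 0.05},
        "beta_noise_sd": {"type": "number", "default": 4.2}
      }
    },
    "output": {
      "type": "object", "additionalProperties": false,
      "properties": {
        "write_events": {"type": "boolean", "default": true},
        "write_bold": {"type": "boolean", "default": false},
        "write_betas": {"type": "boolean", "default": true},
        "bold_format": {"enum": ["nifti"], "default": "nifti"}
      }
    }
  }
}
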