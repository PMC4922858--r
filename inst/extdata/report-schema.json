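{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "cosmosdwell report bundle",
  "description": "Files written by write_report(): events.csv (columns molecule_id, channel, t_bind_s, t_release_s, censored), tally.json, optional fit_release.json and histogram.csv, manifest.json.",
  "type": "object",
  "properties": {
    "tally.json": {
      "type": "object",
      "required": ["total", "counts", "percent"],
      "properties": {
        "total": {"type": "integer", "minimum": 0},
        "counts": {
          "type": "object",
          "required": ["A_FIRST", "B_FIRST", "SIMULTANEOUS_LOSS", "PERSIST"],
          "additionalProperties": {"type": "integer", "minimum": 0}
        },
        "percent": {
          "type": "object",
          "additionalProperties": {"type": "number", "minimum": 0, "maximum": 100}
        }
      }
    },
    "fit_release.json": {
      "type": "object",
      "required": ["model", "par", "loglik", "n", "t_m", "t_max"],
      "properties": {
        "model": {"enum": ["exp1", "exp2", "exp3", "conv"]},
        "par": {"type": "object", "additionalProperties": {"type": "number"}},
        "boot_sd": {"type": ["object", "null"]},
        "loglik": {"type": "number"},
        "n": {"type": "integer", "minimum": 1},
        "t_m": {"type": "number", "minimum": 0},
        "t_max": {"type": "number"}
      }
    },
    "manifest.json": {
      "type": "object",
      "required": ["package", "version", "preset", "n_molecules", "seed"],
      "properties": {
        "package": {"const": "cosmosdwell"},
        "version": {"type": "string"},
        "preset": {"type": "string"},
        "n_molecules": {"type": "integer", "minimum": 0},
        "seed": {"type": "integer"},
        "use_detection": {"type": "boolean"},
        "frame_duration_s": {"type": "number"},
        "frame_spacing_s": {"type": "number"},
        "t_max_s": {"type": "number"}
      }
    }
  }
}
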