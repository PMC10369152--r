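{
  "schema_version": "1.0",
  "title": "fdopapet per-scan summary report",
  "required": ["schema_version", "scan_id", "status", "provenance"],
  "provenance_required": ["software", "version", "config_hash", "seed", "created"],
  "properties": {
    "scan_id": {"type": "string"},
    "status": {"type": "string", "enum": ["ok", "error"]},
    "errors": {"type": "array"},
    "qc": {
      "type": "object",
      "fields": ["reference_frame", "fd", "total_motion_mm", "max_fd_mm",
                 "n_spikes", "flagged", "pass", "reasons"]
    },
    "kinetics": {
      "type": "object",
      "fields": ["ref_region", "t_star", "suvr_window", "regional"]
    },
    "voxelwise": {"type": "object"},
    "provenance": {"type": "object"}
  }
}
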