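# Example data (synthetic)

All tables here are synthetic, generated from the package's phantom presets
(`synthetic_criteria()`, `synthetic_baseline()`). They exist so the grading
pipeline can be exercised end to end; they are **not** clinical reference
values and must not be used for patient data.

- `synthetic_criteria.csv` — per-grade mean/SD of the normalized peak
  signal-intensity difference (columns `grade`, `mu`, `sigma`).
- `synthetic_baseline.csv` — long-format healthy baseline (columns
  `gender`, `age_band`, `segment`, `param`, `mu`, `sigma`).
- `class_map.json` — the canonical 14-class id map.
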