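{
  "schema_version": 1,
  "comment": "Manually specified cross-edition priors P(observed descriptor | edition, hidden 7th-edition descriptor). Editions 5 and 6 share one table (no descriptor changes between them); edition 7 rows are the identity. The hidden-T3 row is split 50-50 between T2 and T3 (>70 mm tumors were T2 in the 6th edition, invasion-based T3 stays T3). The hidden-T4 row keeps most mass on T4 (invasion) with a small spread over T1-T3 for different-ipsilateral-lobe nodule tumors whose underlying primary T is unknown. The M0 row leaks a small probability to M1 for the same nodule tumors, which the 6th edition coded as M1.",
  "T": {
    "T1a": { "T1": 1.0 },
    "T1b": { "T1": 1.0 },
    "T2a": { "T2": 1.0 },
    "T2b": { "T2": 1.0 },
    "T3":  { "T2": 0.5, "T3": 0.5 },
    "T4":  { "T1": 0.05, "T2": 0.05, "T3": 0.05, "T4": 0.85 }
  },
  "M": {
    "M0":  { "M0": 0.98, "M1": 0.02 },
    "M1a": { "M1": 1.0 },
    "M1b": { "M1": 1.0 }
  }
}
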