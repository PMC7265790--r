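{
  "schema_version": 1,
  "comment": "AJCC lung cancer stage grouping for clinically staged NSCLC, M0 cells only; any metastatic M token (M1, M1a, M1b) maps to stage IV regardless of T and N. Occult carcinoma and stage 0 are excluded.",
  "edition6": {
    "T1": { "N0": "IA",  "N1": "IIA",  "N2": "IIIA", "N3": "IIIB" },
    "T2": { "N0": "IB",  "N1": "IIB",  "N2": "IIIA", "N3": "IIIB" },
    "T3": { "N0": "IIB", "N1": "IIIA", "N2": "IIIA", "N3": "IIIB" },
    "T4": { "N0": "IIIB", "N1": "IIIB", "N2": "IIIB", "N3": "IIIB" }
  },
  "edition7": {
    "T1a": { "N0": "IA",   "N1": "IIA",  "N2": "IIIA", "N3": "IIIB" },
    "T1b": { "N0": "IA",   "N1": "IIA",  "N2": "IIIA", "N3": "IIIB" },
    "T2a": { "N0": "IB",   "N1": "IIA",  "N2": "IIIA", "N3": "IIIB" },
    "T2b": { "N0": "IIA",  "N1": "IIB",  "N2": "IIIA", "N3": "IIIB" },
    "T3":  { "N0": "IIB",  "N1": "IIIA", "N2": "IIIA", "N3": "IIIB" },
    "T4":  { "N0": "IIIA", "N1": "IIIA", "N2": "IIIB", "N3": "IIIB" }
  }
}
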