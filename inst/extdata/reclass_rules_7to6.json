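{
  "schema_version": 1,
  "comment": "Declarative 7th-to-6th edition descriptor reclassification rules, inverted from the AJCC 6->7 changes: the 7th edition split T1/T2 by size (<=20, 20-30, 30-50, 50-70 mm), moved >70 mm tumors from T2 to T3, moved same-lobe satellite nodules from T4 to T3, and moved different-ipsilateral-lobe nodules from M1 to T4. T rules are evaluated first-match-wins; 'multifocal'/'sulcus_superior' conditions match true, false, or 'missing' (NA). A missing condition field means the rule applies regardless. 'm_widen' marks rules where the nodule-vs-invasion ambiguity makes the 6th-edition M descriptor undeterminable for M0 tumors.",
  "t_rules": [
    { "t7": "T1a", "t6": ["T1"] },
    { "t7": "T1b", "t6": ["T1"] },
    { "t7": "T1",  "t6": ["T1"] },
    { "t7": "T2a", "t6": ["T2"] },
    { "t7": "T2b", "t6": ["T2"] },
    { "t7": "T2",  "t6": ["T2"] },
    { "t7": "T3", "when": { "multifocal": true },      "t6": ["T4"] },
    { "t7": "T3", "when": { "multifocal": "missing" }, "t6": ["T2", "T3", "T4"] },
    { "t7": "T3", "when": { "sulcus_superior": true }, "t6": ["T3"] },
    { "t7": "T3",                                      "t6": ["T2", "T3"] },
    { "t7": "T4", "when": { "multifocal": true },      "t6": ["T1", "T2", "T3", "T4"], "m_widen": true },
    { "t7": "T4", "when": { "multifocal": "missing" }, "t6": ["T1", "T2", "T3", "T4"], "m_widen": true },
    { "t7": "T4",                                      "t6": ["T4"] },
    { "t7": "TX", "t6": ["TX"] },
    { "t7": "T0", "t6": ["T0"] }
  ],
  "m_rules": {
    "M0":  ["M0"],
    "M1":  ["M1"],
    "M1a": ["M1"],
    "M1b": ["M1"],
    "MX":  ["MX"]
  }
}
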