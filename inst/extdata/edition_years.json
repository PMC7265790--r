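{
  "schema_version": 1,
  "comment": "Default TNM edition in use by incidence year (Dutch registry convention for clinically staged NSCLC).",
  "periods": [
    { "from": 1999, "to": 2002, "edition": "5" },
    { "from": 2003, "to": 2009, "edition": "6" },
    { "from": 2010, "to": 2016, "edition": "7" }
  ]
}
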