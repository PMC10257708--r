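{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "phenoRG pipeline report",
  "type": "object",
  "required": ["meta", "stages"],
  "properties": {
    "meta": {
      "type": "object",
      "required": ["package", "version", "seed", "theta", "dr", "kMax"]
    },
    "stages": {
      "type": "object",
      "statusValues": ["ok", "failed", "skipped"]
    }
  }
}
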