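{
  "autocatalyst": "replicator",
  "sources": ["replicator", "CO2", "dithiol", "ammonia", "thiyl", "coa-thiol"],
  "sinks": ["replicator", "water", "disulfide", "proton", "coa-thiol"],
  "atp_species": ["thiyl"],
  "redox_reduced_species": ["dithiol"],
  "carbon_species": ["CO2"]
}
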