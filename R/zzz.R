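## data.table columns referenced via non-standard evaluation
utils::globalVariables(c(
    "trip", "N", "sample_id", "weight", ".N", "sequence", "start", "end"))
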