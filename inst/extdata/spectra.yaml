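EMS: ["C>T", "G>A"]
transitions: ["C>T", "G>A", "A>G", "T>C"]
none: []
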