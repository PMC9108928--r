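{
  "tool": "harmvis",
  "version": "0.1.0",
  "subcommand": "recommend",
  "outcome-type": "time-to-event",
  "multiplicity": "multiple"
}
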