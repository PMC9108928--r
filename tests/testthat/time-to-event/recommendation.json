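{
  "plots": [],
  "note": "No suitable plot: no endorsed visualisation displays multiple time-to-event outcomes simultaneously; consider separate plots per event."
}
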