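{
  "plots": "dot plot",
  "note": "Comprehensive summary of multiple binary events: absolute risks, a comparative estimate with confidence intervals, and the data table."
}
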