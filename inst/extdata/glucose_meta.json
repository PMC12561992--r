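{
  "slope": 0.051,
  "intercept": -9.38,
  "linear_span_h": [336, 1008],
  "gmax_policy": "max(mean + sd) over intervals starting at or after 2016 h",
  "provenance": "synthetic fixture emulating published hyperglycemic mouse glucose"
}
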