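{
  "default_value": 1,
  "rules": [
    {
      "op": "insert",
      "action": "Pill, on",
      "value": 0.2
    },
    {
      "op": "swap",
      "action": "Pill, on",
      "action2": "Breakfast, on",
      "value": 0.4
    }
  ]
}
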