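{
  "id": "michael_f1",
  "states": ["Alarm, on", "Bathroom, on", "Shower, on", "Shower, off", "Bathroom, off", "Kitchen, on", "Breakfast, on", "Pill, on", "Kitchen, off"],
  "initial_probs": {
    "Alarm, on": 1
  },
  "transitions": [
    {
      "from": "Alarm, on",
      "to": "Bathroom, on",
      "p": 1
    },
    {
      "from": "Bathroom, on",
      "to": "Shower, on",
      "p": 0.6
    },
    {
      "from": "Bathroom, on",
      "to": "Bathroom, off",
      "p": 0.4
    },
    {
      "from": "Shower, on",
      "to": "Shower, off",
      "p": 1
    },
    {
      "from": "Shower, off",
      "to": "Bathroom, off",
      "p": 1
    },
    {
      "from": "Bathroom, off",
      "to": "Kitchen, on",
      "p": 1
    },
    {
      "from": "Kitchen, on",
      "to": "Breakfast, on",
      "p": 1
    },
    {
      "from": "Breakfast, on",
      "to": "Pill, on",
      "p": 1
    },
    {
      "from": "Pill, on",
      "to": "Kitchen, off",
      "p": 1
    }
  ],
  "end_probs": {
    "Kitchen, off": 1
  },
  "terminal_states": "Kitchen, off"
}
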