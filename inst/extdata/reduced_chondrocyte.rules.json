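[
  {
    "watch": "RGD",
    "threshold": 0.5,
    "when_above": [
      "flip_sign: a5b1>actin",
      "remove_edge: FN>a5b1",
      "add_edge: RGD>a5b1:activates",
      "add_edge: a5b1>NFkB:activates"
    ]
  },
  {
    "watch": "RGD",
    "threshold": 0.5,
    "when_above": [
      "flip_sign: aVb3>actin",
      "remove_edge: FN>aVb3",
      "add_edge: RGD>aVb3:activates",
      "add_edge: aVb3>NFkB:activates"
    ]
  }
]
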