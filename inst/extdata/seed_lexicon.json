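{
  "categories": [
    {
      "name": "CombatExposure",
      "parent": null
    },
    {
      "name": "Emotion",
      "parent": null
    },
    {
      "name": "Direct",
      "parent": "CombatExposure"
    },
    {
      "name": "Indirect",
      "parent": "CombatExposure"
    },
    {
      "name": "Protective",
      "parent": "Emotion"
    },
    {
      "name": "Stressful",
      "parent": "Emotion"
    }
  ],
  "entries": [
    {
      "stem": "attack",
      "category": "Direct"
    },
    {
      "stem": "bomb",
      "category": "Indirect",
      "surface_variants": [
        "ied"
      ]
    },
    {
      "stem": "boom",
      "category": "Indirect"
    },
    {
      "stem": "deploy",
      "category": "Indirect"
    },
    {
      "stem": "deton",
      "category": "Indirect"
    },
    {
      "stem": "explos",
      "category": "Indirect"
    },
    {
      "stem": "fire",
      "category": "Direct"
    },
    {
      "stem": "happen",
      "category": "Indirect"
    },
    {
      "stem": "hit",
      "category": "Direct"
    },
    {
      "stem": "hope",
      "category": "Protective"
    },
    {
      "stem": "mission",
      "category": "Indirect"
    },
    {
      "stem": "mortar",
      "category": "Indirect"
    },
    {
      "stem": "nervou",
      "category": "Stressful"
    },
    {
      "stem": "patrol",
      "category": "Direct"
    },
    {
      "stem": "safe",
      "category": "Protective"
    },
    {
      "stem": "scare",
      "category": "Stressful"
    },
    {
      "stem": "secur",
      "category": "Protective"
    },
    {
      "stem": "see",
      "category": "Indirect"
    },
    {
      "stem": "shot",
      "category": "Direct"
    },
    {
      "stem": "soldier",
      "category": "Indirect"
    },
    {
      "stem": "stop",
      "category": "Indirect"
    },
    {
      "stem": "support",
      "category": "Protective"
    },
    {
      "stem": "truck",
      "category": "Indirect"
    },
    {
      "stem": "upset",
      "category": "Stressful"
    },
    {
      "stem": "vehicl",
      "category": "Indirect"
    },
    {
      "stem": "weapon",
      "category": "Direct"
    }
  ]
}
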