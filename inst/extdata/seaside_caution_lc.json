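{
  "format_version": 1,
  "name": "seaside_caution_LC",
  "constraint_level": "LC",
  "sorts": [
    {
      "name": "entity",
      "parent": null
    },
    {
      "name": "person",
      "parent": "entity"
    },
    {
      "name": "object",
      "parent": "entity"
    }
  ],
  "attributes": {
    "sentient": ["yes", "no"],
    "can_move": ["yes", "no"],
    "in_danger": ["yes", "no"],
    "location": ["water", "beach"],
    "afloat": ["yes", "no"]
  },
  "categories": {
    "caution_theme": {
      "sort": "entity",
      "distributions": {
        "sentient": {
          "yes": 0.95,
          "no": 0.05
        },
        "can_move": {
          "yes": 0.95,
          "no": 0.05
        },
        "in_danger": {
          "yes": 0.9,
          "no": 0.1
        },
        "location": {
          "water": 0.95,
          "beach": 0.05
        },
        "afloat": {
          "yes": 0.9,
          "no": 0.1
        }
      }
    },
    "swimmer": {
      "sort": "person",
      "distributions": {
        "sentient": {
          "yes": 0.99,
          "no": 0.01
        },
        "can_move": {
          "yes": 0.99,
          "no": 0.01
        },
        "in_danger": {
          "yes": 0.85,
          "no": 0.15
        },
        "location": {
          "water": 0.9,
          "beach": 0.1
        },
        "afloat": {
          "yes": 0.85,
          "no": 0.15
        }
      }
    },
    "trainee": {
      "sort": "person",
      "distributions": {
        "sentient": {
          "yes": 0.99,
          "no": 0.01
        },
        "can_move": {
          "yes": 0.99,
          "no": 0.01
        },
        "in_danger": {
          "yes": 0.6,
          "no": 0.4
        },
        "location": {
          "water": 0.5,
          "beach": 0.5
        },
        "afloat": {
          "yes": 0.5,
          "no": 0.5
        }
      }
    },
    "drawer": {
      "sort": "object",
      "distributions": {
        "location": {
          "water": 0.02,
          "beach": 0.98
        },
        "afloat": {
          "yes": 0.1,
          "no": 0.9
        }
      }
    }
  },
  "arg_concept": {
    "category": "caution_theme",
    "context_independent": [
      "sentient",
      "can_move",
      "in_danger"
    ],
    "context_dependent": [],
    "threshold_r": 0.5,
    "contrasts": [
      {
        "name": "danger_on_beach",
        "distributions": {
          "location": {
            "water": 0.05,
            "beach": 0.95
          },
          "afloat": {
            "yes": 0.1,
            "no": 0.9
          }
        }
      }
    ],
    "provenance": {
      "fixture_choice": "all probabilities"
    }
  },
  "prenominal_updates": [],
  "critical_words": {
    "swimmers": {
      "category": "swimmer"
    },
    "trainees": {
      "category": "trainee"
    },
    "drawer": {
      "category": "drawer"
    }
  },
  "roles": null
}
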