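{
  "format_version": 1,
  "name": "holiday_resort",
  "constraint_level": "HC",
  "sorts": [
    {
      "name": "plant",
      "parent": null
    },
    {
      "name": "tree",
      "parent": "plant"
    },
    {
      "name": "flower",
      "parent": "plant"
    }
  ],
  "attributes": {
    "habitat": ["tropics", "moderate"],
    "height": ["tall", "small"]
  },
  "categories": {
    "planting_theme": {
      "sort": "plant",
      "distributions": {
        "habitat": {
          "tropics": 0.9,
          "moderate": 0.1
        },
        "height": {
          "tall": 0.6,
          "small": 0.4
        }
      }
    },
    "palm": {
      "sort": "tree",
      "distributions": {
        "habitat": {
          "tropics": 0.9,
          "moderate": 0.1
        },
        "height": {
          "tall": 0.8,
          "small": 0.2
        }
      }
    },
    "pine": {
      "sort": "tree",
      "distributions": {
        "habitat": {
          "tropics": 0.1,
          "moderate": 0.9
        },
        "height": {
          "tall": 0.8,
          "small": 0.2
        }
      }
    },
    "tulip": {
      "sort": "flower",
      "distributions": {
        "habitat": {
          "tropics": 0.1,
          "moderate": 0.9
        },
        "height": {
          "tall": 0.2,
          "small": 0.8
        }
      }
    }
  },
  "arg_concept": {
    "category": "planting_theme",
    "context_independent": [],
    "context_dependent": [
      "habitat",
      "height"
    ],
    "threshold_r": 0.5,
    "contrasts": [
      {
        "name": "moderate_look",
        "distributions": {
          "habitat": {
            "tropics": 0.1,
            "moderate": 0.9
          }
        }
      }
    ],
    "provenance": {
      "printed": ["planting_theme distributions", "contrast habitat 0.1/0.9 (cue-validity 0.9/0.1)"],
      "fixture_choice": "palm/pine/tulip distributions"
    }
  },
  "prenominal_updates": [],
  "critical_words": {
    "palms": {
      "category": "palm"
    },
    "pines": {
      "category": "pine"
    },
    "tulips": {
      "category": "tulip"
    }
  },
  "roles": null
}
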