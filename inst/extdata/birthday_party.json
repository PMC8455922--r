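{
  "format_version": 1,
  "name": "birthday_party",
  "constraint_level": "HC",
  "sorts": [
    {
      "name": "food",
      "parent": null
    }
  ],
  "attributes": {
    "taste": ["sweet", "not_sweet"],
    "nutrition_value": ["healthy", "not_healthy"],
    "served_at": ["birthday_party", "not_birthday_party"]
  },
  "categories": {
    "dessert_arg": {
      "sort": "food",
      "distributions": {
        "taste": {
          "sweet": 0.95,
          "not_sweet": 0.05
        },
        "nutrition_value": {
          "healthy": 0.05,
          "not_healthy": 0.95
        },
        "served_at": {
          "birthday_party": 0.98,
          "not_birthday_party": 0.02
        }
      }
    },
    "cake": {
      "sort": "food",
      "distributions": {
        "taste": {
          "sweet": 0.9,
          "not_sweet": 0.1
        },
        "nutrition_value": {
          "healthy": 0.2,
          "not_healthy": 0.8
        },
        "served_at": {
          "birthday_party": 0.98,
          "not_birthday_party": 0.02
        }
      }
    },
    "veggies": {
      "sort": "food",
      "distributions": {
        "taste": {
          "sweet": 0.2,
          "not_sweet": 0.8
        },
        "nutrition_value": {
          "healthy": 0.9,
          "not_healthy": 0.1
        },
        "served_at": {
          "birthday_party": 0.02,
          "not_birthday_party": 0.98
        }
      }
    }
  },
  "arg_concept": {
    "category": "dessert_arg",
    "context_independent": [],
    "context_dependent": [
      "taste",
      "nutrition_value",
      "served_at"
    ],
    "threshold_r": 0.5,
    "diagnosticity": {
      "taste": 0.45,
      "nutrition_value": 0.1,
      "served_at": 0.45
    }
  },
  "prenominal_updates": {
    "sweet": {
      "chain": "taste",
      "value": "sweet",
      "revisions": {
        "nutrition_value": {
          "healthy": 0.02,
          "not_healthy": 0.98
        }
      }
    },
    "healthy": {
      "chain": "nutrition_value",
      "value": "healthy",
      "revisions": {
        "taste": {
          "sweet": 0.4,
          "not_sweet": 0.6
        },
        "served_at": {
          "birthday_party": 0.95,
          "not_birthday_party": 0.05
        }
      }
    }
  },
  "critical_words": {
    "cake": {
      "category": "cake"
    },
    "veggies": {
      "category": "veggies"
    }
  },
  "roles": null
}
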