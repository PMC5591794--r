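{
  "structures": [
    {
      "code": "N",
      "label": "nose",
      "canonical_order": 1
    },
    {
      "code": "V",
      "label": "velum",
      "canonical_order": 2
    },
    {
      "code": "Ts",
      "label": "tonsils",
      "canonical_order": 3
    },
    {
      "code": "O",
      "label": "lateral pharyngeal wall/oropharynx",
      "canonical_order": 4
    },
    {
      "code": "Tb",
      "label": "tongue base",
      "canonical_order": 5
    },
    {
      "code": "E",
      "label": "epiglottis",
      "canonical_order": 6
    },
    {
      "code": "L",
      "label": "larynx",
      "canonical_order": 7
    }
  ],
  "degrees": [
    {
      "value": 0,
      "label": "none",
      "band": "<50%"
    },
    {
      "value": 1,
      "label": "partial",
      "band": "50-75%"
    },
    {
      "value": 2,
      "label": "complete",
      "band": ">75%"
    }
  ],
  "configurations": [
    {
      "code": "AP",
      "label": "anteroposterior"
    },
    {
      "code": "L",
      "label": "lateral"
    },
    {
      "code": "C",
      "label": "concentric"
    }
  ],
  "allowed_configurations": {
    "N": [],
    "V": ["AP", "L", "C"],
    "Ts": "L",
    "O": ["AP", "L", "C"],
    "Tb": ["AP", "L", "C"],
    "E": ["AP", "L"],
    "L": []
  },
  "systems": {
    "PRINGLE": {
      "label": "Pringle and Croft grading",
      "sites": null,
      "grades": [1, 2, 3, 4, 5]
    },
    "VOTE": {
      "label": "VOTE (velum, oropharynx, tongue base, epiglottis)",
      "sites": {
        "V": {
          "grades": [0, 1, 2],
          "configurations": ["AP", "L", "C"]
        },
        "O": {
          "grades": [0, 1, 2],
          "configurations": "L"
        },
        "T": {
          "grades": [0, 1, 2],
          "configurations": "AP"
        },
        "E": {
          "grades": [0, 1, 2],
          "configurations": ["AP", "L"]
        }
      },
      "grades": null
    },
    "NOHL": {
      "label": "NOHL (nose, oropharynx, hypopharynx, larynx)",
      "sites": {
        "N": {
          "grades": [1, 2, 3, 4],
          "configurations": []
        },
        "O": {
          "grades": [1, 2, 3, 4],
          "configurations": ["AP", "t", "C"]
        },
        "H": {
          "grades": [1, 2, 3, 4],
          "configurations": ["AP", "L", "C"]
        },
        "Ts": {
          "grades": [1, 2, 3, 4],
          "configurations": []
        },
        "L": {
          "flags": ["N", "P"],
          "configurations": []
        }
      },
      "grades": null
    },
    "PTLTBE": {
      "label": "P-T-L-Tb-E (palate, tonsils, lateral wall, tongue base, epiglottis)",
      "sites": {
        "P": {
          "grades": [1, 2, 3],
          "configurations": []
        },
        "T": {
          "grades": [1, 2, 3],
          "configurations": []
        },
        "L": {
          "grades": [1, 2, 3],
          "configurations": []
        },
        "Tb": {
          "grades": [1, 2, 3],
          "configurations": []
        },
        "E": {
          "grades": [1, 2],
          "configurations": []
        }
      },
      "grades": null
    }
  }
}
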