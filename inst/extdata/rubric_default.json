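{
  "age_years": {
    "type": "numeric",
    "bins": [
      {
        "lower": 0,
        "upper": 26,
        "points": 1,
        "lower_closed": true,
        "upper_closed": false
      },
      {
        "lower": 26,
        "upper": 32,
        "points": 2,
        "lower_closed": true,
        "upper_closed": false
      },
      {
        "lower": 32,
        "upper": null,
        "points": 3,
        "lower_closed": true,
        "upper_closed": false
      }
    ]
  },
  "n_muscles": {
    "type": "numeric",
    "bins": [
      {
        "lower": 0,
        "upper": 1,
        "points": 0,
        "lower_closed": true,
        "upper_closed": false
      },
      {
        "lower": 1,
        "upper": 2,
        "points": 1,
        "lower_closed": true,
        "upper_closed": false
      },
      {
        "lower": 2,
        "upper": 3,
        "points": 2,
        "lower_closed": true,
        "upper_closed": false
      },
      {
        "lower": 3,
        "upper": null,
        "points": 3,
        "lower_closed": true,
        "upper_closed": false
      }
    ]
  },
  "location": {
    "type": "categorical",
    "levels": {
      "none": 0,
      "proximal": 1,
      "middle": 2,
      "distal": 3
    }
  },
  "insertion": {
    "type": "categorical",
    "levels": {
      "no": 0,
      "yes": 2
    }
  },
  "transverse_pct": {
    "type": "numeric",
    "bins": [
      {
        "lower": 0,
        "upper": 25,
        "points": 0,
        "lower_closed": true,
        "upper_closed": false
      },
      {
        "lower": 25,
        "upper": 50,
        "points": 1,
        "lower_closed": true,
        "upper_closed": false
      },
      {
        "lower": 50,
        "upper": 75,
        "points": 2,
        "lower_closed": true,
        "upper_closed": false
      },
      {
        "lower": 75,
        "upper": null,
        "points": 3,
        "lower_closed": true,
        "upper_closed": false
      }
    ]
  },
  "retraction_cm": {
    "type": "numeric",
    "bins": [
      {
        "lower": 0,
        "upper": 0,
        "points": 0,
        "lower_closed": true,
        "upper_closed": true
      },
      {
        "lower": 0,
        "upper": 2,
        "points": 1,
        "lower_closed": false,
        "upper_closed": false
      },
      {
        "lower": 2,
        "upper": null,
        "points": 2,
        "lower_closed": true,
        "upper_closed": false
      }
    ]
  },
  "sagittal_cm": {
    "type": "numeric",
    "bins": [
      {
        "lower": 0,
        "upper": 0,
        "points": 0,
        "lower_closed": true,
        "upper_closed": true
      },
      {
        "lower": 0,
        "upper": 5,
        "points": 1,
        "lower_closed": false,
        "upper_closed": false
      },
      {
        "lower": 5,
        "upper": 10,
        "points": 2,
        "lower_closed": true,
        "upper_closed": false
      },
      {
        "lower": 10,
        "upper": null,
        "points": 3,
        "lower_closed": true,
        "upper_closed": false
      }
    ]
  }
}
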