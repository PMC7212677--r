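{
  "compartments": [
    {"id": "unscreened", "label": "Unscreened prevalent"},
    {"id": "screened", "label": "Screened positive"},
    {"id": "in_care", "label": "Linked to care"},
    {"id": "death", "label": "Deceased", "terminal": true}
  ],
  "transitions": [
    {"source": "unscreened", "target": "screened", "base_rate": 0.2, "driver": "screening"},
    {"source": "screened", "target": "in_care", "base_rate": 0.5}
  ],
  "demography": {
    "annual_incident_cases": 100,
    "background_mortality": 0.01,
    "excess_mortality": {"unscreened": 0.005},
    "entry_compartment": "unscreened",
    "death_compartment": "death"
  },
  "initial_counts": {"unscreened": 2000, "screened": 50, "in_care": 400},
  "initial_year": 2016
}
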