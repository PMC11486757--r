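[
  {
    "map_name": "toy_branched_tca.synthetic_layout",
    "map_description": "Synthetic minimal pathway-map layout for the toy branched catabolism network (hand-written; not derived from any published map).",
    "homepage": "",
    "schema": "1-0-0"
  },
  {
    "reactions": {
      "1": {"bigg_id": "EX_s", "name": "substrate exchange"},
      "2": {"bigg_id": "ED_NP", "name": "non-phosphorylative branch"},
      "3": {"bigg_id": "ED_SP1", "name": "semi-phosphorylative branch step 1"},
      "4": {"bigg_id": "ED_SP2", "name": "semi-phosphorylative branch step 2"},
      "5": {"bigg_id": "TCA", "name": "TCA-like ATP regeneration"},
      "6": {"bigg_id": "BIOMASS", "name": "biomass formation"}
    },
    "nodes": {},
    "text_labels": {},
    "canvas": {"x": 0, "y": 0, "width": 600, "height": 400}
  }
]
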