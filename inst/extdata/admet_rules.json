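[
  {"property": "caco2", "kind": "threshold", "label": "Caco-2 permeability",
   "comparator": "gt", "threshold": 0.90, "note_band": 0.2,
   "verdict_true": "high Caco-2 permeability",
   "verdict_false": "not high Caco-2 permeability"},
  {"property": "intestinal_absorption", "kind": "threshold",
   "label": "human intestinal absorption", "comparator": "lt", "threshold": 30,
   "verdict_true": "poorly absorbed", "verdict_false": "adequately absorbed"},
  {"property": "skin_logkp", "kind": "threshold", "label": "skin permeability",
   "comparator": "gt", "threshold": -2.5,
   "verdict_true": "low skin permeability",
   "verdict_false": "skin permeable"},
  {"property": "bbb_logbb", "kind": "threshold", "label": "BBB crossing",
   "comparator": "gt", "threshold": -0.3,
   "verdict_true": "readily crosses BBB",
   "verdict_false": "does not readily cross BBB"},
  {"property": "bbb_logbb", "kind": "threshold", "label": "brain distribution",
   "comparator": "lt", "threshold": -1,
   "verdict_true": "poorly distributed to brain",
   "verdict_false": "adequately distributed to brain"},
  {"property": "cns_logps", "kind": "report", "label": "CNS permeability"},
  {"property": "tpyriformis", "kind": "threshold",
   "label": "T. pyriformis toxicity", "comparator": "gt", "threshold": -0.5,
   "verdict_true": "toxic to T. pyriformis",
   "verdict_false": "not toxic to T. pyriformis"},
  {"property": "vdss", "kind": "report", "label": "steady-state volume of distribution"},
  {"property": "fraction_unbound", "kind": "report", "label": "fraction unbound in plasma"},
  {"property": "total_clearance", "kind": "report", "label": "total clearance"},
  {"property": "max_tolerated_dose", "kind": "report", "label": "maximum tolerated dose"},
  {"property": "orat_ld50", "kind": "report", "label": "oral rat acute toxicity LD50"},
  {"property": "orct", "kind": "report", "label": "oral rat chronic toxicity"},
  {"property": "pgp_substrate", "kind": "flag", "label": "P-glycoprotein substrate",
   "verdict_true": "P-gp substrate", "verdict_false": "not a P-gp substrate"},
  {"property": "pgp1_inhibitor", "kind": "flag", "label": "P-glycoprotein I inhibitor",
   "verdict_true": "P-gp I inhibitor", "verdict_false": "not a P-gp I inhibitor"},
  {"property": "pgp2_inhibitor", "kind": "flag", "label": "P-glycoprotein II inhibitor",
   "verdict_true": "P-gp II inhibitor", "verdict_false": "not a P-gp II inhibitor"},
  {"property": "cyp2d6_substrate", "kind": "flag", "label": "CYP2D6 substrate",
   "verdict_true": "CYP2D6 substrate", "verdict_false": "not a CYP2D6 substrate"},
  {"property": "cyp3a4_substrate", "kind": "flag", "label": "CYP3A4 substrate",
   "verdict_true": "CYP3A4 substrate", "verdict_false": "not a CYP3A4 substrate"},
  {"property": "cyp1a2_inhibitor", "kind": "flag", "label": "CYP1A2 inhibitor",
   "verdict_true": "CYP1A2 inhibitor", "verdict_false": "not a CYP1A2 inhibitor"},
  {"property": "cyp2c19_inhibitor", "kind": "flag", "label": "CYP2C19 inhibitor",
   "verdict_true": "CYP2C19 inhibitor", "verdict_false": "not a CYP2C19 inhibitor"},
  {"property": "cyp2c9_inhibitor", "kind": "flag", "label": "CYP2C9 inhibitor",
   "verdict_true": "CYP2C9 inhibitor", "verdict_false": "not a CYP2C9 inhibitor"},
  {"property": "cyp2d6_inhibitor", "kind": "flag", "label": "CYP2D6 inhibitor",
   "verdict_true": "CYP2D6 inhibitor", "verdict_false": "not a CYP2D6 inhibitor"},
  {"property": "cyp3a4_inhibitor", "kind": "flag", "label": "CYP3A4 inhibitor",
   "verdict_true": "CYP3A4 inhibitor", "verdict_false": "not a CYP3A4 inhibitor"},
  {"property": "oct2_substrate", "kind": "flag", "label": "renal OCT2 substrate",
   "verdict_true": "OCT2 substrate", "verdict_false": "not an OCT2 substrate"},
  {"property": "ames", "kind": "flag", "label": "AMES mutagenicity",
   "verdict_true": "mutagenic (AMES positive)", "verdict_false": "not mutagenic"},
  {"property": "herg1", "kind": "flag", "label": "hERG I inhibition",
   "verdict_true": "hERG I inhibitor", "verdict_false": "not an hERG I inhibitor"},
  {"property": "herg2", "kind": "flag", "label": "hERG II inhibition",
   "verdict_true": "hERG II inhibitor", "verdict_false": "not an hERG II inhibitor"},
  {"property": "hepatotoxicity", "kind": "flag", "label": "hepatotoxicity",
   "verdict_true": "hepatotoxic", "verdict_false": "not hepatotoxic"},
  {"property": "skin_sensitisation", "kind": "flag", "label": "skin sensitisation",
   "verdict_true": "skin sensitiser", "verdict_false": "not a skin sensitiser"}
]
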