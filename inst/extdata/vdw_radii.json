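{
  "_comment": "Bondi-style van der Waals radii (Angstrom), keyed by element symbol.",
  "H": 1.20,
  "C": 1.70,
  "N": 1.55,
  "O": 1.52,
  "P": 1.80,
  "S": 1.80,
  "F": 1.47,
  "CL": 1.75,
  "BR": 1.85,
  "I": 1.98,
  "MG": 1.73,
  "NA": 2.27,
  "K": 2.75,
  "CA": 2.31,
  "ZN": 1.39,
  "MN": 2.00,
  "FE": 2.00
}
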