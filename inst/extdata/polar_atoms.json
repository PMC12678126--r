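{
  "_comment": "Hydrogen-bond donor/acceptor heavy atoms and formal charge groups at pH 7. 'backbone' applies to every standard amino-acid residue; per-residue entries add side-chain atoms. Charged sets drive the charge-class energy scale (1/2/4 kcal/mol).",
  "backbone": {
    "donors": ["N"],
    "acceptors": ["O", "OXT"],
    "charged_positive": [],
    "charged_negative": ["OXT"]
  },
  "residues": {
    "ARG": { "donors": ["NE", "NH1", "NH2"], "acceptors": [], "charged_positive": ["NE", "NH1", "NH2"], "charged_negative": [] },
    "LYS": { "donors": ["NZ"], "acceptors": [], "charged_positive": ["NZ"], "charged_negative": [] },
    "HIS": { "donors": ["ND1", "NE2"], "acceptors": ["ND1", "NE2"], "charged_positive": ["ND1", "NE2"], "charged_negative": [] },
    "ASP": { "donors": [], "acceptors": ["OD1", "OD2"], "charged_positive": [], "charged_negative": ["OD1", "OD2"] },
    "GLU": { "donors": [], "acceptors": ["OE1", "OE2"], "charged_positive": [], "charged_negative": ["OE1", "OE2"] },
    "SER": { "donors": ["OG"], "acceptors": ["OG"], "charged_positive": [], "charged_negative": [] },
    "THR": { "donors": ["OG1"], "acceptors": ["OG1"], "charged_positive": [], "charged_negative": [] },
    "TYR": { "donors": ["OH"], "acceptors": ["OH"], "charged_positive": [], "charged_negative": [] },
    "ASN": { "donors": ["ND2"], "acceptors": ["OD1"], "charged_positive": [], "charged_negative": [] },
    "GLN": { "donors": ["NE2"], "acceptors": ["OE1"], "charged_positive": [], "charged_negative": [] },
    "TRP": { "donors": ["NE1"], "acceptors": [], "charged_positive": [], "charged_negative": [] },
    "CYS": { "donors": ["SG"], "acceptors": ["SG"], "charged_positive": [], "charged_negative": [] },
    "ATP": {
      "donors": ["N6", "O2'", "O3'"],
      "acceptors": ["O1A", "O2A", "O3A", "O1B", "O2B", "O3B", "O1G", "O2G", "O3G", "O2'", "O3'", "O4'", "O5'", "N1", "N3", "N7"],
      "charged_positive": [],
      "charged_negative": ["O1A", "O2A", "O1B", "O2B", "O1G", "O2G", "O3G"]
    },
    "ADP": {
      "donors": ["N6", "O2'", "O3'"],
      "acceptors": ["O1A", "O2A", "O3A", "O1B", "O2B", "O3B", "O2'", "O3'", "O4'", "O5'", "N1", "N3", "N7"],
      "charged_positive": [],
      "charged_negative": ["O1A", "O2A", "O1B", "O2B", "O3B"]
    },
    "DA": { "donors": ["N6"], "acceptors": ["OP1", "OP2", "O3'", "O4'", "O5'", "N1", "N3", "N7"], "charged_positive": [], "charged_negative": ["OP1", "OP2"] },
    "DT": { "donors": ["N3"], "acceptors": ["OP1", "OP2", "O3'", "O4'", "O5'", "O2", "O4"], "charged_positive": [], "charged_negative": ["OP1", "OP2"] },
    "DG": { "donors": ["N1", "N2"], "acceptors": ["OP1", "OP2", "O3'", "O4'", "O5'", "O6", "N3", "N7"], "charged_positive": [], "charged_negative": ["OP1", "OP2"] },
    "DC": { "donors": ["N4"], "acceptors": ["OP1", "OP2", "O3'", "O4'", "O5'", "O2", "N3"], "charged_positive": [], "charged_negative": ["OP1", "OP2"] }
  }
}
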