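{
  "_comment": "Titratable-site library: reference pKa values, site kind, and the per-atom charge sets of the protonated/deprotonated states (simplified formal-charge model; neutral states carry zero charge). Histidine is modelled as two coupled proton sites (NE2 / ND1) carrying half charges so that the doubly protonated microstate sums to +1 and the neutral tautomers to 0; the doubly deprotonated (imidazolate) microstate is excluded by a configurable penalty.",
  "sites": {
    "ASP": { "kind": "acid", "pka_ref": 4.0,  "q_prot": 0.0, "q_deprot": -1.0,
             "atoms_prot": {}, "atoms_deprot": { "OD1": -0.5, "OD2": -0.5 } },
    "GLU": { "kind": "acid", "pka_ref": 4.4,  "q_prot": 0.0, "q_deprot": -1.0,
             "atoms_prot": {}, "atoms_deprot": { "OE1": -0.5, "OE2": -0.5 } },
    "CYS": { "kind": "acid", "pka_ref": 9.5,  "q_prot": 0.0, "q_deprot": -1.0,
             "atoms_prot": {}, "atoms_deprot": { "SG": -1.0 } },
    "TYR": { "kind": "acid", "pka_ref": 9.6,  "q_prot": 0.0, "q_deprot": -1.0,
             "atoms_prot": {}, "atoms_deprot": { "OH": -1.0 } },
    "LYS": { "kind": "base", "pka_ref": 10.4, "q_prot": 1.0, "q_deprot": 0.0,
             "atoms_prot": { "NZ": 1.0 }, "atoms_deprot": {} },
    "ARG": { "kind": "base", "pka_ref": 12.0, "q_prot": 1.0, "q_deprot": 0.0,
             "atoms_prot": { "NH1": 0.4, "NH2": 0.4, "NE": 0.2 }, "atoms_deprot": {} },
    "HIS_NE2": { "kind": "base", "pka_ref": 7.0, "q_prot": 0.5, "q_deprot": -0.5,
                 "atoms_prot": { "NE2": 0.5 }, "atoms_deprot": { "NE2": -0.5 } },
    "HIS_ND1": { "kind": "base", "pka_ref": 6.6, "q_prot": 0.5, "q_deprot": -0.5,
                 "atoms_prot": { "ND1": 0.5 }, "atoms_deprot": { "ND1": -0.5 } }
  },
  "imidazolate_penalty": 10.0,
  "background_charges": {
    "ATP": { "O1A": -0.5, "O2A": -0.5, "O1B": -0.5, "O2B": -0.5,
             "O1G": -0.6667, "O2G": -0.6667, "O3G": -0.6667 },
    "ADP": { "O1A": -0.5, "O2A": -0.5,
             "O1B": -0.6667, "O2B": -0.6667, "O3B": -0.6667 },
    "DA": { "OP1": -0.5, "OP2": -0.5 },
    "DT": { "OP1": -0.5, "OP2": -0.5 },
    "DG": { "OP1": -0.5, "OP2": -0.5 },
    "DC": { "OP1": -0.5, "OP2": -0.5 }
  }
}
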