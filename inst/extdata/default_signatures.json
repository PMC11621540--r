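{
  "well-differentiated": {
    "genes": ["SFTPC", "SFTPB", "SFTPA1", "NAPSA", "SCGB3A2", "NKX2-1"],
    "category": "tumor-feature",
    "class": "well-differentiated"
  },
  "proliferative": {
    "genes": ["MKI67", "TOP2A", "CCNB1", "WEE1", "PCNA", "FOS"],
    "category": "tumor-feature",
    "class": "proliferative"
  },
  "invasive": {
    "genes": ["MMP7", "TNC", "TGFBI", "SPINK1", "VIM", "RHOB"],
    "category": "tumor-feature",
    "class": "invasive"
  },
  "B cell": {
    "genes": ["MS4A1", "CD79A", "CD19", "IGHM", "CXCR5"],
    "category": "microenvironment-feature",
    "class": "B cell"
  },
  "T cell": {
    "genes": ["CD3E", "CD3D", "CD2", "TRAC", "IL7R"],
    "category": "microenvironment-feature",
    "class": "T cell"
  },
  "fibroblast-CAF": {
    "genes": ["COL1A1", "COL1A2", "ACTA2", "SPARC", "PDGFRB"],
    "category": "microenvironment-feature",
    "class": "fibroblast-CAF"
  },
  "macrophage": {
    "genes": ["CD68", "MARCO", "LYZ", "SPP1", "MRC1"],
    "category": "microenvironment-feature",
    "class": "macrophage"
  }
}
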