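{
  "metadata": {
    "name": "pathmeta bundled toy model",
    "version": "1.0"
  },
  "compounds": [
    {
      "id": "glucose",
      "name": "glucose",
      "monoisotopic_mass": 180.063388,
      "aliases": ["d-glucose", "dextrose"]
    },
    {
      "id": "g6p",
      "name": "glucose 6-phosphate",
      "monoisotopic_mass": 260.029719,
      "aliases": []
    },
    {
      "id": "pyruvate",
      "name": "pyruvate",
      "monoisotopic_mass": 88.016044,
      "aliases": "pyruvic acid"
    },
    {
      "id": "lactate",
      "name": "lactate",
      "monoisotopic_mass": 90.031694,
      "aliases": "lactic acid"
    },
    {
      "id": "tyrosine",
      "name": "tyrosine",
      "monoisotopic_mass": 181.073893,
      "aliases": "l-tyrosine"
    },
    {
      "id": "phenylalanine",
      "name": "phenylalanine",
      "monoisotopic_mass": 165.078979,
      "aliases": "l-phenylalanine"
    },
    {
      "id": "tryptophan",
      "name": "tryptophan",
      "monoisotopic_mass": 204.089878,
      "aliases": "l-tryptophan"
    },
    {
      "id": "ornithine",
      "name": "ornithine",
      "monoisotopic_mass": 132.089878,
      "aliases": "l-ornithine"
    },
    {
      "id": "putrescine",
      "name": "putrescine",
      "monoisotopic_mass": 88.100048,
      "aliases": []
    },
    {
      "id": "spermidine",
      "name": "spermidine",
      "monoisotopic_mass": 145.157898,
      "aliases": []
    },
    {
      "id": "spermine",
      "name": "spermine",
      "monoisotopic_mass": 202.215747,
      "aliases": []
    },
    {
      "id": "acetylspermidine",
      "name": "N1-acetylspermidine",
      "monoisotopic_mass": 187.168462,
      "aliases": []
    }
  ],
  "pathways": [
    {
      "id": "P1",
      "name": "Glycolysis and gluconeogenesis",
      "compound_ids": ["g6p", "glucose", "lactate", "pyruvate"],
      "gene_symbols": ["GPI", "HK1", "LDHA", "PKM"],
      "uniprot_ids": ["P00338", "P06744", "P14618", "P19367"]
    },
    {
      "id": "P4",
      "name": "Polyamine metabolism",
      "compound_ids": ["acetylspermidine", "ornithine", "putrescine", "spermidine", "spermine"],
      "gene_symbols": ["AMD1", "ODC1", "SAT1", "SMS", "SRM"],
      "uniprot_ids": ["P11926", "P19623", "P21673", "P52788"]
    },
    {
      "id": "P9",
      "name": "Tyrosine and tryptophan metabolism",
      "compound_ids": ["phenylalanine", "tryptophan", "tyrosine"],
      "gene_symbols": ["IDO1", "TAT", "TH", "TPH1"],
      "uniprot_ids": ["P07101", "P14902", "P17735", "P17752"]
    }
  ]
}
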