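[
  {
    "gene": "SLC6A4",
    "rs_id": "rs25531",
    "wild_genotype": "AA",
    "minor_allele": "G",
    "n_wild": 174,
    "n_hetero": 57,
    "n_mutant": 0
  },
  {
    "gene": "FKBP5",
    "rs_id": "rs9296158",
    "wild_genotype": "GG",
    "minor_allele": "A",
    "n_wild": 115,
    "n_hetero": 98,
    "n_mutant": 18
  },
  {
    "gene": "FKBP5",
    "rs_id": "rs3800373",
    "wild_genotype": "AA",
    "minor_allele": "C",
    "n_wild": 148,
    "n_hetero": 71,
    "n_mutant": 12
  },
  {
    "gene": "FKBP5",
    "rs_id": "rs1360780",
    "wild_genotype": "CC",
    "minor_allele": "T",
    "n_wild": 144,
    "n_hetero": 74,
    "n_mutant": 13
  },
  {
    "gene": "FKBP5",
    "rs_id": "rs9470080",
    "wild_genotype": "CC",
    "minor_allele": "T",
    "n_wild": 111,
    "n_hetero": 100,
    "n_mutant": 20
  },
  {
    "gene": "FKBP5",
    "rs_id": "rs4713916",
    "wild_genotype": "GG",
    "minor_allele": "A",
    "n_wild": 146,
    "n_hetero": 74,
    "n_mutant": 11
  },
  {
    "gene": "FKBP5",
    "rs_id": "rs4713919",
    "wild_genotype": "GG",
    "minor_allele": "A",
    "n_wild": 130,
    "n_hetero": 82,
    "n_mutant": 19
  },
  {
    "gene": "FKBP5",
    "rs_id": "rs6902321",
    "wild_genotype": "TT",
    "minor_allele": "C",
    "n_wild": 118,
    "n_hetero": 97,
    "n_mutant": 16
  },
  {
    "gene": "FKBP5",
    "rs_id": "rs56311918",
    "wild_genotype": "TT",
    "minor_allele": "C",
    "n_wild": 168,
    "n_hetero": 59,
    "n_mutant": 4
  },
  {
    "gene": "FKBP5",
    "rs_id": "rs3798345",
    "wild_genotype": "CC",
    "minor_allele": "T",
    "n_wild": 157,
    "n_hetero": 66,
    "n_mutant": 8
  },
  {
    "gene": "ADCYAP1R1",
    "rs_id": "rs2267735",
    "wild_genotype": "CC",
    "minor_allele": "G",
    "n_wild": 59,
    "n_hetero": 119,
    "n_mutant": 53
  },
  {
    "gene": "BDNF",
    "rs_id": "rs6265",
    "wild_genotype": "CC",
    "minor_allele": "T",
    "n_wild": 75,
    "n_hetero": 108,
    "n_mutant": 48
  },
  {
    "gene": "COMT",
    "rs_id": "rs4680",
    "wild_genotype": "GG",
    "minor_allele": "A",
    "n_wild": 116,
    "n_hetero": 102,
    "n_mutant": 13
  },
  {
    "gene": "COMT",
    "rs_id": "rs4633",
    "wild_genotype": "CC",
    "minor_allele": "T",
    "n_wild": 119,
    "n_hetero": 100,
    "n_mutant": 12
  },
  {
    "gene": "HTR3A",
    "rs_id": "rs1062613",
    "wild_genotype": "CC",
    "minor_allele": "T",
    "n_wild": 194,
    "n_hetero": 34,
    "n_mutant": 3
  },
  {
    "gene": "DRD2",
    "rs_id": "rs2075652",
    "wild_genotype": "GG",
    "minor_allele": "A",
    "n_wild": 86,
    "n_hetero": 99,
    "n_mutant": 46
  },
  {
    "gene": "NR3C1",
    "rs_id": "rs258747",
    "wild_genotype": "AA",
    "minor_allele": "G",
    "n_wild": 125,
    "n_hetero": 89,
    "n_mutant": 17
  },
  {
    "gene": "OXTR",
    "rs_id": "rs53576",
    "wild_genotype": "AA",
    "minor_allele": "G",
    "n_wild": 92,
    "n_hetero": 99,
    "n_mutant": 40
  }
]
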