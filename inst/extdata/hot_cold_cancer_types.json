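{
  "hot": ["BLCA", "BRCA", "CESC", "COAD", "READ", "HNSC", "KIRC", "LIHC",
          "LUAD", "LUSC", "LUNG", "MESO", "OV", "PAAD", "PRAD", "SKCM",
          "STAD", "UCEC"],
  "cold": ["ACC", "CHOL", "DLBC", "ESCA", "KICH", "KIRP", "TGCT", "THCA",
           "THYM", "UCS", "UVM", "GBM", "LGG", "PCPG", "SARC"]
}
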