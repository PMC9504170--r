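# CYP2C19 allele-function registry.
# Classes: normal, decreased, none (loss of function), increased, uncertain.
# Extend by adding "<star allele>: <class>" entries; the phenotype rule
# engine is total over any pair of these classes.
alleles:
  "*1": normal
  "*2": none
  "*3": none
  "*9": decreased
  "*12": uncertain
  "*14": uncertain
  "*17": increased
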