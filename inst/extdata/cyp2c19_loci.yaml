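loci:
- id: rs4244285
  rsid: rs4244285
  allele_name: CYP2C19*2
  position_label: '681'
  position: 22
  major: G
  minor: A
- id: rs4986893
  rsid: rs4986893
  allele_name: CYP2C19*3
  position_label: '636'
  position: 20
  major: G
  minor: A
- id: rs12248560
  rsid: rs12248560
  allele_name: CYP2C19*17
  position_label: '806'
  position: 20
  major: C
  minor: T
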