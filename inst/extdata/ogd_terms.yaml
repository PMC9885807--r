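# Term set for the oxygen-glucose deprivation (OGD) exemplar.
# Multiword phrases match with any run of space/hyphen/slash between
# words (dash glyphs are folded before matching); the abbreviation is
# matched case-sensitively at word boundaries.
terms:
  - phrase: [oxygen, glucose, deprivation]
    variants:
      - [oxygen, and, glucose, deprivation]
      - [deprived, of, oxygen, and, glucose]
      - [deprivation, of, oxygen, and, glucose]
      - [glucose, and, oxygen, deprivation]
    abbrev: OGD
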