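# Default item -> facet allocation across the five instruments.
# Provenance "rational-default": the published supplementary allocation
# table is not redistributable, so this table is reconstructed from the
# named facets, the published composite memberships, and rational analysis
# of item content. Replace freely via read_facet_allocation().
# The Tension facet is always dropped downstream (see build_facets()).
# Items listed under "unallocated" have no directly relevant facet and are
# excluded with reason "no_relevant_factor".
facets:
  DepressedMood:
    items: [QIDS5, QIDS15, BDI1, MADRS1, MADRS2, MADRS6, MADRS8, HAMD1, HAMD7, HAMD8]
  Anhedonia:
    items: [SHAPS1, SHAPS2, SHAPS3, SHAPS4, SHAPS5, SHAPS6, SHAPS7, SHAPS8,
            SHAPS9, SHAPS10, SHAPS11, SHAPS12, SHAPS13, SHAPS14]
  Amotivation:
    items: [QIDS10, QIDS13, QIDS14, BDI4, BDI11, BDI12, BDI13, BDI15, BDI17,
            BDI21, MADRS7, HAMD13, HAMD14]
  NegativeCognition:
    items: [QIDS11, BDI2, BDI3, BDI5, BDI6, BDI7, BDI8, BDI10, BDI14, HAMD2, MADRS9]
  ImpairedSleep:
    items: [QIDS1, QIDS2, QIDS3, QIDS4, BDI16, HAMD4, HAMD5, HAMD6, MADRS4]
  ReducedAppetite:
    items: [QIDS6, QIDS8, BDI18, BDI19, HAMD12, HAMD16, MADRS5]
  SuicidalThoughts:
    items: [QIDS12, MADRS10, BDI9, HAMD3]
  Tension:
    items: [QIDS16, MADRS3, HAMD9, HAMD10, HAMD11]
unallocated: [QIDS7, QIDS9, HAMD15, HAMD17, BDI20]
provenance: rational-default
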