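# Default marker registry: the 23-protein + 1-FISH panel used for IHC/FISH
# subclassification of newly diagnosed glioblastoma. One entry per marker.
#   scheme              one of: binary_alteration, quartile_0to3, triad_0to2,
#                       quad_intensity_0to3, basal_1to2, proliferation_fraction
#   designated_subclass pre-designated subclass association used for cluster
#                       labelling and pruning (PN, CLAS, MES, NEURAL, PROLIF, OTHER)
#   is_genetic          marker directly/indirectly reflects a genetic abnormality;
#                       exempt from standardization before clustering
#   excluded            dropped before any expression analysis (no differential
#                       staining pattern)
markers:
  - {name: IDH1_R132H, scheme: binary_alteration,      designated_subclass: PN,     is_genetic: true,  excluded: false}
  - {name: DLL3,       scheme: quartile_0to3,          designated_subclass: PN,     is_genetic: false, excluded: true}
  - {name: OLIG2,      scheme: quartile_0to3,          designated_subclass: PN,     is_genetic: false, excluded: false}
  - {name: p53,        scheme: triad_0to2,             designated_subclass: PN,     is_genetic: false, excluded: false}
  - {name: PDGFRA,     scheme: basal_1to2,             designated_subclass: PN,     is_genetic: false, excluded: false}
  - {name: EGFR,       scheme: binary_alteration,      designated_subclass: CLAS,   is_genetic: true,  excluded: false}
  - {name: EGFRvIII,   scheme: binary_alteration,      designated_subclass: CLAS,   is_genetic: true,  excluded: false}
  - {name: EGFR_FISH,  scheme: binary_alteration,      designated_subclass: CLAS,   is_genetic: true,  excluded: false}
  - {name: CD44,       scheme: quad_intensity_0to3,    designated_subclass: MES,    is_genetic: false, excluded: false}
  - {name: FN1,        scheme: triad_0to2,             designated_subclass: MES,    is_genetic: false, excluded: false}
  - {name: GFAP,       scheme: basal_1to2,             designated_subclass: MES,    is_genetic: false, excluded: false}
  - {name: MET,        scheme: quad_intensity_0to3,    designated_subclass: MES,    is_genetic: false, excluded: false}
  - {name: NES,        scheme: basal_1to2,             designated_subclass: MES,    is_genetic: false, excluded: false}
  - {name: NF1,        scheme: basal_1to2,             designated_subclass: MES,    is_genetic: false, excluded: false}
  - {name: PTEN,       scheme: triad_0to2,             designated_subclass: MES,    is_genetic: false, excluded: false}
  - {name: STAT3,      scheme: basal_1to2,             designated_subclass: MES,    is_genetic: false, excluded: false}
  - {name: VIM,        scheme: triad_0to2,             designated_subclass: MES,    is_genetic: false, excluded: false}
  - {name: YKL40,      scheme: basal_1to2,             designated_subclass: MES,    is_genetic: false, excluded: false}
  - {name: CHGA,       scheme: triad_0to2,             designated_subclass: NEURAL, is_genetic: false, excluded: false}
  - {name: NeuN,       scheme: quartile_0to3,          designated_subclass: NEURAL, is_genetic: false, excluded: false}
  - {name: NEFL,       scheme: triad_0to2,             designated_subclass: NEURAL, is_genetic: false, excluded: false}
  - {name: SYP,        scheme: quad_intensity_0to3,    designated_subclass: NEURAL, is_genetic: false, excluded: false}
  - {name: Ki67,       scheme: proliferation_fraction, designated_subclass: PROLIF, is_genetic: false, excluded: false}
  - {name: TOP2A,      scheme: proliferation_fraction, designated_subclass: PROLIF, is_genetic: false, excluded: false}
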