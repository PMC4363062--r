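# ICRP-103 tissue weighting factors for the tissues present in an ankle
# study. Muscle and lymphatic nodes are remainder organs sharing the
# collective remainder weight, split over the 13-tissue remainder set.
w_T: {bone_marrow: 0.12, bone_surface: 0.01, skin: 0.01}
w_remainder: 0.12
remainder_members: [muscle, lymphatic_nodes]
remainder_count: 13
w_R: 1
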