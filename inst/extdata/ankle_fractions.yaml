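# Default fractions irradiated for the six-layer ankle phantom.
# Provenance of the regional totals: red marrow 0.7% (calf, MRI volumetry)
# + 0.4% (foot, cadaver data) of whole-body marrow mass split per bone;
# bone surface 4.9% of whole-body bone surface; skin sites 0.9% + 2.6% of
# whole-body skin area (Du Bois); muscle 0.9% of 28 kg whole-body muscle;
# lymphatic nodes 1% of whole-body nodes. Talus marrow (dosimeter 15) has
# no default fraction and is left unassigned.
entries:
- {tissue: bone_marrow, subunit: tibia, f_i: 0.007, dosimeters: [1, 4, 7, 9], aggregation: mean_then_fraction}
- {tissue: bone_marrow, subunit: fibula, f_i: 0.001, dosimeters: [6, 11], aggregation: mean_then_fraction}
- {tissue: bone_marrow, subunit: navicular, f_i: 0.001, dosimeters: [14], aggregation: mean_then_fraction}
- {tissue: bone_marrow, subunit: metatarsals, f_i: 0.001, dosimeters: [16], aggregation: mean_then_fraction}
- {tissue: bone_marrow, subunit: calcaneus, f_i: 0.002, dosimeters: [18], aggregation: mean_then_fraction}
- {tissue: bone_surface, subunit: calcaneal_tuberosity, f_i: 0.049, dosimeters: [13, 19], aggregation: per_site_fraction}
- {tissue: skin, subunit: superior_extensor_retinaculum, f_i: 0.009, dosimeters: [8], aggregation: per_site_fraction}
- {tissue: skin, subunit: calcaneal_tendon, f_i: 0.026, dosimeters: [10], aggregation: per_site_fraction}
- {tissue: muscle, subunit: ankle_muscles, f_i: 0.009, dosimeters: [2, 3, 5, 20], aggregation: group_mean}
- {tissue: lymphatic_nodes, subunit: ankle_nodes, f_i: 0.010, dosimeters: [12, 17], aggregation: group_mean}
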