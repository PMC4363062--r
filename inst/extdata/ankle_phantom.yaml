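# Six-layer anthropomorphic ankle phantom with twenty MOSFET placements.
# depth_mm is a nominal depth below the surface, used only by the synthetic
# dose-field generator (the physical placement grid does not record it).
layers:
- {index: 23, thickness_mm: 25}
- {index: 24, thickness_mm: 25}
- {index: 25, thickness_mm: 25}
- {index: 26, thickness_mm: 25}
- {index: 27, thickness_mm: 25}
- {index: 28, thickness_mm: 25}
dosimeters:
- {dosimeter_no: 1, layer: 23, site: Tibia, tissue: bone_marrow, subunit: tibia, depth_mm: 35}
- {dosimeter_no: 2, layer: 23, site: Peroneus brevis, tissue: muscle, subunit: peroneus_brevis, depth_mm: 20}
- {dosimeter_no: 3, layer: 23, site: Gastrocnemius, tissue: muscle, subunit: gastrocnemius, depth_mm: 20}
- {dosimeter_no: 4, layer: 24, site: Tibia, tissue: bone_marrow, subunit: tibia, depth_mm: 35}
- {dosimeter_no: 5, layer: 24, site: Tibialis anterior, tissue: muscle, subunit: tibialis_anterior, depth_mm: 20}
- {dosimeter_no: 6, layer: 25, site: Fibula, tissue: bone_marrow, subunit: fibula, depth_mm: 35}
- {dosimeter_no: 7, layer: 25, site: Tibia, tissue: bone_marrow, subunit: tibia, depth_mm: 35}
- {dosimeter_no: 8, layer: 26, site: Superior extensor retinaculum, tissue: skin, subunit: superior_extensor_retinaculum, depth_mm: 1}
- {dosimeter_no: 9, layer: 26, site: Tibia, tissue: bone_marrow, subunit: tibia, depth_mm: 35}
- {dosimeter_no: 10, layer: 26, site: Calcaneal tendon, tissue: skin, subunit: calcaneal_tendon, depth_mm: 1}
- {dosimeter_no: 11, layer: 26, site: Fibula, tissue: bone_marrow, subunit: fibula, depth_mm: 35}
- {dosimeter_no: 12, layer: 26, site: Lymph vein, tissue: lymphatic_nodes, subunit: ankle_nodes, depth_mm: 15}
- {dosimeter_no: 13, layer: 27, site: Posterior calcaneal tuberosity, tissue: bone_surface, subunit: calcaneal_tuberosity, depth_mm: 30}
- {dosimeter_no: 14, layer: 27, site: Navicular, tissue: bone_marrow, subunit: navicular, depth_mm: 30}
- {dosimeter_no: 15, layer: 27, site: Talus, tissue: bone_marrow, subunit: talus, depth_mm: 30}
- {dosimeter_no: 16, layer: 28, site: Metatarsals, tissue: bone_marrow, subunit: metatarsals, depth_mm: 25}
- {dosimeter_no: 17, layer: 28, site: Lymph vein, tissue: lymphatic_nodes, subunit: ankle_nodes, depth_mm: 15}
- {dosimeter_no: 18, layer: 28, site: Calcaneus, tissue: bone_marrow, subunit: calcaneus, depth_mm: 30}
- {dosimeter_no: 19, layer: 28, site: Calcaneal tuberosity, tissue: bone_surface, subunit: calcaneal_tuberosity, depth_mm: 30}
- {dosimeter_no: 20, layer: 28, site: Flexor digitorum brevis, tissue: muscle, subunit: flexor_digitorum_brevis, depth_mm: 20}
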