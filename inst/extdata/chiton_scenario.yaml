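# Karyotype evolutionary route of the chitons from a 20-linkage-group
# molluscan ancestor, as an executable rearrangement scenario.
#
# Seven tip genomes (one gastropod, one bivalve, five chitons) descend from
# an ancestor of 20 linkage groups. Fusions on the polyplacophoran stem
# (4+16+18, 7+10, 8+9) are synapomorphies of the living chitons; the
# Chitonida sensu lato stem adds linkage group 1 to the 4+16+18 chromosome.
# Lineage fusions bring the tips to 1n = 20/20 (outgroups), 11
# (Deshayesiella), 13 (Callochiton), 14 (Liolophura, 15 with the optional
# duplication), and 8/8 (the two Acanthochitona congeners, via two different
# fusions each from their 1n = 10 common ancestor). Linkage groups 19 and 20
# are never touched. Branch lengths are in My; root-to-tip depth 540 My,
# Acanthochitona congeners diverged 23 My ago.
name: chiton-karyotype-route
tree: >-
  ((Gibbula_magus:530,Mizuhopecten_yessoensis:530)Conchifera:10,
  (Deshayesiella_sirenkoi:340,(Callochiton_septemvalvis:300,
  (Liolophura_japonica:260,(Acanthochitona_rubrolineata:23,
  Acanthochitona_discrepans:23)Acanthochitona:237)Chitonida:40)
  ChitonidaSL:40)Polyplacophora:200)Mollusca;
n_lgs: 20
# strictly decreasing member counts (so inferred numbering matches the
# ancestral numbering); total 4729 markers
lg_sizes: [350, 338, 326, 314, 303, 291, 279, 267, 255, 243,
           232, 220, 208, 196, 184, 172, 161, 149, 137, 104]
tip_noise: 0.0
events:
  - {branch: Polyplacophora, type: FUSION, lgs: [4, 16]}
  - {branch: Polyplacophora, type: FUSION, lgs: [4, 18]}
  - {branch: Polyplacophora, type: FUSION, lgs: [7, 10]}
  - {branch: Polyplacophora, type: FUSION, lgs: [8, 9]}
  - {branch: ChitonidaSL, type: FUSION, lgs: [1, 4]}
  - {branch: Deshayesiella_sirenkoi, type: FUSION, lgs: [2, 12]}
  - {branch: Deshayesiella_sirenkoi, type: FUSION, lgs: [3, 17]}
  - {branch: Deshayesiella_sirenkoi, type: FUSION, lgs: [5, 15]}
  - {branch: Deshayesiella_sirenkoi, type: FUSION, lgs: [6, 13]}
  - {branch: Deshayesiella_sirenkoi, type: FUSION, lgs: [1, 11]}
  - {branch: Callochiton_septemvalvis, type: FUSION, lgs: [2, 5]}
  - {branch: Callochiton_septemvalvis, type: FUSION, lgs: [3, 6]}
  - {branch: Liolophura_japonica, type: FUSION, lgs: [11, 17]}
  - {branch: Acanthochitona, type: FUSION, lgs: [2, 3]}
  - {branch: Acanthochitona, type: FUSION, lgs: [14, 15]}
  - {branch: Acanthochitona, type: FUSION, lgs: [2, 14]}
  - {branch: Acanthochitona, type: FUSION, lgs: [5, 6]}
  - {branch: Acanthochitona, type: FUSION, lgs: [12, 13]}
  - {branch: Acanthochitona_rubrolineata, type: FUSION, lgs: [5, 11]}
  - {branch: Acanthochitona_rubrolineata, type: FUSION, lgs: [12, 17]}
  - {branch: Acanthochitona_discrepans, type: FUSION, lgs: [7, 8]}
  - {branch: Acanthochitona_discrepans, type: FUSION, lgs: [11, 14]}
# optional events modelling the Liolophura partial genome duplication
# (two linkage groups fused first, the fused chromosome then duplicated);
# applied only when the scenario is simulated with duplication = TRUE
duplication_events:
  - {branch: Liolophura_japonica, type: DUPLICATION, lgs: [11]}
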