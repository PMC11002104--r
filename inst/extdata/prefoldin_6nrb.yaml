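# Prefoldin hexamer analysis template (PDB entries 6NR8, 6NR9, 6NRB, 6NRC,
# 6NRD: prefoldin in complex with chaperonin TRiC/CCT, classes 2-6).
#
# TEMPLATE: the deposited files contain many chaperonin chains besides the
# six prefoldin subunits, and the stem ("beta-sheets") / tentacle
# ("helices") partitions are secondary-structure-derived residue ranges
# that must come from an external assignment (e.g. DSSP) — they are not
# shipped here. Fill in:
#   * chains: the six prefoldin chain IDs of the deposited file, in file
#     order (reported as Chain 1..6),
#   * partitions: the beta-sheet stem, helical tentacle and non-helical
#     residue ranges per chain.
# The whole-complex, per-chain component and per-chain individual rows are
# then produced by analyze_complex(); this config drives the same analysis
# through fod_analyze() for a chosen chain subset.
id: prefoldin_6nrb
structure: 6NRB.pdb
params:
  scale: kyte_doolittle
  cutoff: 9.0
  sigma_rule: extent3
  sigma_floor: 1.0
  k_max: 10.0
  k_step: 0.01
  interface_threshold: 9.0
units:
  - label: PFD complex
    mode: individual
    chains: [FILL_IN_1, FILL_IN_2, FILL_IN_3, FILL_IN_4, FILL_IN_5, FILL_IN_6]
partitions:
  - label: Helices
    ranges: []      # tentacle (helical) ranges per chain
  - label: Beta-sheets
    ranges: []      # stem (beta + unordered) ranges per chain
  - label: No helices
    ranges: []      # everything outside the helical ranges
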