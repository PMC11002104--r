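# Tubulin analysis: alpha-tubulin chain A of PDB entry 1FFX (stathmin-like
# complex; chains A, C = tubulin alpha-1; B, D = tubulin beta; E = stathmin
# helix). Domain ranges are CATH-derived config data. P-P status of chain A
# residues is taken against all other chains of the complex.
id: tubulin_1ffx
structure: 1FFX.pdb
params:
  scale: kyte_doolittle
  cutoff: 9.0
  sigma_rule: extent3
  sigma_floor: 1.0
  k_max: 10.0
  k_step: 0.01
  interface_threshold: 9.0
units:
  - label: 1FFX Chain A
    mode: individual
    chains: [A]
    partners: {chains: [B, C, D, E]}
  - label: Dom1 (part of chain)
    mode: component
    parent: {chains: [A]}
    ranges:
      - {chain: A, start: 1, end: 268}
    partners: {chains: [B, C, D, E]}
  - label: Dom2 (part of chain)
    mode: component
    parent: {chains: [A]}
    ranges:
      - {chain: A, start: 269, end: 383}
    partners: {chains: [B, C, D, E]}
  - label: Dom3 (part of chain)
    mode: component
    parent: {chains: [A]}
    ranges:
      - {chain: A, start: 384, end: 440}
    partners: {chains: [B, C, D, E]}
  - label: Dom1 (individual)
    mode: individual
    ranges:
      - {chain: A, start: 1, end: 268}
    partners: {chains: [B, C, D, E]}
  - label: Dom2 (individual)
    mode: individual
    ranges:
      - {chain: A, start: 269, end: 383}
    partners: {chains: [B, C, D, E]}
  - label: Dom3 (individual)
    mode: individual
    ranges:
      - {chain: A, start: 384, end: 440}
    partners: {chains: [B, C, D, E]}
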