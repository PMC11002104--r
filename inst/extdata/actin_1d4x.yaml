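# Actin analysis: mg-ATP actin chain A of PDB entry 1D4X (complex with a
# gelsolin segment). Domain ranges are CATH-derived config data; the chain
# row is analyzed whole, each domain both as a component of the chain and
# as an individual unit, with P-P (inter-chain contact) status against the
# gelsolin partner chain. Partner chain IDs follow the deposited file.
id: actin_1d4x
structure: 1D4X.pdb
params:
  scale: kyte_doolittle
  cutoff: 9.0
  sigma_rule: extent3
  sigma_floor: 1.0
  k_max: 10.0
  k_step: 0.01
  interface_threshold: 9.0
units:
  - label: 1D4X Chain A
    mode: individual
    chains: [A]
  - label: Domain 1 (part of chain)
    mode: component
    parent: {chains: [A]}
    ranges:
      - {chain: A, start: 4, end: 137}
      - {chain: A, start: 339, end: 373}
    partners: {chains: [G]}
  - label: Domain 2 (part of chain)
    mode: component
    parent: {chains: [A]}
    ranges:
      - {chain: A, start: 138, end: 179}
      - {chain: A, start: 272, end: 338}
    partners: {chains: [G]}
  - label: Domain 3 (part of chain)
    mode: component
    parent: {chains: [A]}
    ranges:
      - {chain: A, start: 180, end: 271}
    partners: {chains: [G]}
  - label: Domain 1 (individual)
    mode: individual
    ranges:
      - {chain: A, start: 4, end: 137}
      - {chain: A, start: 339, end: 373}
    partners: {chains: [G]}
  - label: Domain 2 (individual)
    mode: individual
    ranges:
      - {chain: A, start: 138, end: 179}
      - {chain: A, start: 272, end: 338}
    partners: {chains: [G]}
  - label: Domain 3 (individual)
    mode: individual
    ranges:
      - {chain: A, start: 180, end: 271}
    partners: {chains: [G]}
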