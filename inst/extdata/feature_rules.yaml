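# Pharmacophore feature perception rules, version 1.
# These are the standard public feature definitions; edit and pass the file
# to perceive_features(rules = read_feature_rules(path)) to override.
version: 1
donor:
  # N-H / O-H groups; anions that lost their proton simply have no H left
  elements: ["N", "O"]
  require_hydrogen: true
acceptor:
  elements: ["N", "O"]
  exclude_nitrogen:
    - amide            # N single-bonded to a carbonyl carbon
    - pyrrole_type     # aromatic N carrying a hydrogen
    - positive_charge
    - oxidized         # N bonded to oxygen (nitro, N-oxide)
hydrophobe:
  elements: ["C", "F", "Cl", "Br", "I"]
  min_cluster_size: 2
  polar_neighbors: ["N", "O", "S", "P"]   # atoms adjacent to these are not hydrophobic
  exclude_charged: true
ring_aromatic:
  sizes: [5, 6]
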