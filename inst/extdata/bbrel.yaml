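# Bacteria-Biotope relation task: entity types, relation categories and the
# unordered type pairs each category may link. Edit `pairs` to change the
# constraint rules; `roles` are the argument names written to .a2 lines.
name: bbrel
entity_types: [Microorganism, Habitat, Geographical, Phenotype]
type_priority: [Microorganism]
categories:
  - name: Lives_In
    roles: [Microorganism, Location]
    pairs:
      - [Microorganism, Habitat]
      - [Microorganism, Geographical]
  - name: Exhibits
    roles: [Microorganism, Property]
    pairs:
      - [Microorganism, Phenotype]
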