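# Seed-development binary relation task. The official legal-triple table is
# not bundled: every category below licenses any type pair ("*" wildcard).
# Replace the wildcard pairs with the task documentation's constraint table
# before using this configuration on real corpora.
name: seedev
entity_types:
  - Gene
  - Gene_Family
  - Box
  - Promoter
  - RNA
  - Protein
  - Protein_Family
  - Protein_Complex
  - Protein_Domain
  - Hormone
  - Regulatory_Network
  - Pathway
  - Genotype
  - Tissue
  - Development_Phase
  - Environmental_Factor
type_priority: []
categories:
  - {name: Exists_In_Genotype,            roles: [Element, Genotype],    pairs: [["*", "*"]]}
  - {name: Occurs_In_Genotype,            roles: [Process, Genotype],    pairs: [["*", "*"]]}
  - {name: Exists_At_Stage,               roles: [Functional_Molecule, Development], pairs: [["*", "*"]]}
  - {name: Occurs_During,                 roles: [Process, Development], pairs: [["*", "*"]]}
  - {name: Is_Localized_In,               roles: [Functional_Molecule, Target_Tissue], pairs: [["*", "*"]]}
  - {name: Is_Involved_In_Process,        roles: [Participant, Process], pairs: [["*", "*"]]}
  - {name: Transcribes_Or_Translates_To,  roles: [Source, Product],      pairs: [["*", "*"]]}
  - {name: Is_Functionally_Equivalent_To, roles: [Element1, Element2],   pairs: [["*", "*"]]}
  - {name: Regulates_Accumulation,        roles: [Agent, Functional_Molecule], pairs: [["*", "*"]]}
  - {name: Regulates_Development_Phase,   roles: [Agent, Development],   pairs: [["*", "*"]]}
  - {name: Regulates_Expression,          roles: [Agent, DNA],           pairs: [["*", "*"]]}
  - {name: Regulates_Molecule_Activity,   roles: [Agent, Molecule],      pairs: [["*", "*"]]}
  - {name: Regulates_Process,             roles: [Agent, Process],       pairs: [["*", "*"]]}
  - {name: Regulates_Tissue_Development,  roles: [Agent, Target_Tissue], pairs: [["*", "*"]]}
  - {name: Composes_Primary_Structure,    roles: [DNA_Part, DNA],        pairs: [["*", "*"]]}
  - {name: Composes_Protein_Complex,      roles: [Amino_Acid_Sequence, Protein_Complex], pairs: [["*", "*"]]}
  - {name: Is_Protein_Domain_Of,          roles: [Domain, Product],      pairs: [["*", "*"]]}
  - {name: Is_Member_Of_Family,           roles: [Element, Family],      pairs: [["*", "*"]]}
  - {name: Has_Sequence_Identical_To,     roles: [Element1, Element2],   pairs: [["*", "*"]]}
  - {name: Interacts_With,                roles: [Agent, Target],        pairs: [["*", "*"]]}
  - {name: Binds_To,                      roles: [Functional_Molecule, Molecule], pairs: [["*", "*"]]}
  - {name: Is_Linked_To,                  roles: [Agent1, Agent2],       pairs: [["*", "*"]]}
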