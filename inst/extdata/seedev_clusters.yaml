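# Category -> cluster mapping for cluster-level evaluation of the
# seed-development task. The official cluster membership table is not bundled;
# this default grouping follows the category names and is meant to be edited
# against the task documentation.
comparison:
  - Is_Functionally_Equivalent_To
  - Has_Sequence_Identical_To
function:
  - Exists_In_Genotype
  - Occurs_In_Genotype
  - Exists_At_Stage
  - Occurs_During
  - Is_Localized_In
  - Is_Involved_In_Process
  - Transcribes_Or_Translates_To
regulation:
  - Regulates_Accumulation
  - Regulates_Development_Phase
  - Regulates_Process
  - Regulates_Tissue_Development
  - Is_Linked_To
genic_regulation:
  - Regulates_Expression
  - Regulates_Molecule_Activity
composition_membership:
  - Composes_Primary_Structure
  - Composes_Protein_Complex
  - Is_Protein_Domain_Of
  - Is_Member_Of_Family
interaction:
  - Interacts_With
  - Binds_To
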