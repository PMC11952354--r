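# Demo schema: a small Biolink-flavoured semantic layer with two symmetric
# predicates and two canonical inverse pairs. Default schema for
# fixture_spec() and for configs that do not name a schema_file.
categories:
  - name: NamedThing
  - name: ChemicalEntity
    parents: [NamedThing]
  - name: Drug
    parents: [ChemicalEntity]
  - name: SmallMolecule
    parents: [ChemicalEntity]
  - name: BiologicalEntity
    parents: [NamedThing]
  - name: Gene
    parents: [BiologicalEntity]
  - name: Protein
    parents: [BiologicalEntity]
  - name: DiseaseOrPhenotypicFeature
    parents: [NamedThing]
  - name: Disease
    parents: [DiseaseOrPhenotypicFeature]
  - name: PhenotypicFeature
    parents: [DiseaseOrPhenotypicFeature]
predicates:
  - name: related_to
  - name: interacts_with
    parents: [related_to]
    symmetric: true
  - name: associated_with
    parents: [related_to]
    symmetric: true
  - name: affects
    parents: [related_to]
  - name: treats
    parents: [affects]
    canonical: true
    inverse: treated_by
  - name: treated_by
    parents: [related_to]
    inverse: treats
  - name: regulates
    parents: [affects]
    canonical: true
    inverse: regulated_by
  - name: regulated_by
    parents: [related_to]
    inverse: regulates
  - name: subclass_of
    parents: [related_to]
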