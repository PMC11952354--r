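id	subject	predicate	object	primary_knowledge_source	publications
T001	CHEBI:46195	interacts_with	UniProtKB:P23219	infores:drugbank	PMID:100001
T002	CHEBI:46195	interacts_with	UniProtKB:P35354	infores:drugbank
T003	CHEBI:46195	treats	MONDO:0002048	infores:drugcentral	PMID:100002|PMID:100003
T004	MONDO:0005277	subclass_of	MONDO:0002048	infores:mondo
T005	MONDO:0100096	subclass_of	MONDO:0002048	infores:mondo
T006	MONDO:0005277	treated_by	CHEBI:15365	infores:semmeddb	PMID:100004
T007	NCBIGene:5743	associated_with	MONDO:0005277	infores:ctd
T008	CHEBI:15365	interacts_with	UniProtKB:P23219	infores:drugbank
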