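id	name	category	equivalent_identifiers
CHEBI:46195	acetaminophen	Drug	CHEBI:46195|DRUGBANK:DB00316
CHEBI:15365	acetylsalicylic acid	Drug	CHEBI:15365|DRUGBANK:DB00945
UniProtKB:P23219	PTGS1	Protein
UniProtKB:P35354	PTGS2	Protein
NCBIGene:5743	PTGS2 gene	Gene
MONDO:0002048	headache disorder	Disease
MONDO:0005277	migraine	Disease
MONDO:0100096	tension-type headache	Disease
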