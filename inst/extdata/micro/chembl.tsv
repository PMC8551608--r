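drug_id	target_id	pchembl	organism_class	target_type	family_members	gene_symbol	evidence
CHEMBL10	P10001	5.00	human	single_protein		ALPHA	assay
CHEMBL10	FAMILY-1	7.00	human	protein_family	P10002;P10003		assay
CHEMBL10	RAT-GAMMA	6.20	mammal_nonhuman	single_protein		GAMMA	assay
CHEMBL10	P10004	4.90	human	single_protein		DELTA	assay
CHEMBL20	P10007	8.00	human	single_protein		ETA	assay
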