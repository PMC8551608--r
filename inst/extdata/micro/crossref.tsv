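namespace_a	id_a	namespace_b	id_b
uniprot_acc	P10001	gene_symbol	ALPHA
uniprot_acc	P10002	gene_symbol	BETA
uniprot_acc	P10003	gene_symbol	GAMMA
uniprot_acc	P10004	gene_symbol	DELTA
uniprot_acc	P10005	gene_symbol	EPSIL
uniprot_acc	P10006	gene_symbol	ZETA
uniprot_acc	P10007	gene_symbol	ETA
uniprot_acc	P10008	gene_symbol	THETA
uniprot_name	EPSIL_HUMAN	uniprot_acc	P10005
drugbank	DB00001	chembl	CHEMBL10
pubchem	111	chembl	CHEMBL10
pharmgkb	PA0001	chembl	CHEMBL20
iuphar_ligand	555	chembl	CHEMBL20
iuphar_target	2472	uniprot_acc	P10006
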