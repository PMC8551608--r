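gene_symbol	tissue	ntpm
ALPHA	heart	5.000
BETA	heart	30.000
GAMMA	heart	1.000
DELTA	heart	3.000
EPSIL	heart	0.200
ZETA	heart	10.000
ETA	heart	0.000
THETA	heart	2.000
ALPHA	liver	0.500
BETA	liver	1.000
GAMMA	liver	0.000
DELTA	liver	50.000
EPSIL	liver	7.000
ZETA	liver	0.100
ETA	liver	4.000
THETA	liver	0.000
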