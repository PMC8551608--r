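R-HSA-300001	Top-level category	P10001	P10002	P10003	P10004	P10005	P10006	P10007	P10008
R-HSA-100001	Cardiac repolarisation micro pathway	P10001	P10002	P10003
R-HSA-100002	Bile transport micro pathway	P10004	P10005	P10006
R-HSA-100003	Xenobiotic metabolism micro pathway	P10006	P10007	P10008
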