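molecule_chembl_id,Names,stIds,fdrs,pValues
CHEMBL10,Cardiac repolarisation micro pathway,R-HSA-100001,0.03571428571,0.01785714286
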