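CHEMBL10
CHEMBL20
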