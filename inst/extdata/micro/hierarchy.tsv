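parent	child
R-HSA-300001	R-HSA-100001
R-HSA-300001	R-HSA-100002
R-HSA-300001	R-HSA-100003
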