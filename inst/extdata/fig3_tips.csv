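taxon,shape
G0,gray
G1,gray
L1,red
L2,gold
L3,red
L4,red
L5,gold
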