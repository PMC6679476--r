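(G0:1,G1:1,(L1:1,L2:1)t1:1,(L3:1,L4:1)t2:1,L5:1)root;
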