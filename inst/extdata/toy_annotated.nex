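#NEXUS
[ synthetic example of a BEAST-style annotated tree ]
begin trees;
  translate
    1 alpha,
    2 beta,
    3 gamma,
    4 delta;
  tree TREE1 = [&R] (((1[&loc="X"]:1.2,2[&loc="X"]:0.8)[&loc="X"]:0.5,3[&loc="Y"]:1.6)[&loc.set={"X","Y"},loc.set.prob={0.85,0.15}]:0.4,4[&loc="Y"]:2.1)[&loc="Y"];
end;
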