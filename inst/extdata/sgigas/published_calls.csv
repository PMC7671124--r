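mass_id,min_sires,parentage
20,1,EP
21,1,
23,1,
25,1,
26,2,
27,1,MO
28,1,
29,1,
30,1,EP
31,1,
32,2,
33,1,EP
34,1,
35,1,
36,1,
37,2,
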