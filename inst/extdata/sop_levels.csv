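code,level
1,4
2,2
3,3
4,3
5,2
6,1
7,1
8,1
9,2
10,1
11,2
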