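id,pre,post
1,3.71,4.07
2,3.87,4.25
3,4.12,4.28
4,3.95,4.02
5,3.69,3.90
6,4.21,4.39
7,3.80,4.15
8,3.77,3.98
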