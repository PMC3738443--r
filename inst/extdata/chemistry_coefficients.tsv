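c0	c1	c2
0.001514	0.3323	0.7411
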