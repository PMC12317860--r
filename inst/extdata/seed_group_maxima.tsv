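group	max_distance
1	0.0651
2	0.0442
3b	0.0564
4	0.0482
5	0.0482
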