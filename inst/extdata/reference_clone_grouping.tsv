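group	sample_id
1	SHC2
1	SHC3
2	HEL1
2	HEL2
3b	OH
3b	HKP1
3b	HKP3
3b	HKP4
3b	HKP5
3b	HKP6
3b	HKP7
3b	STHI
3b	KT
4	KJL1
4	KJL2
4	UNK11
5	SAL1
5	SAL2
5	SAL3
5	NMT4
5	WC
6	HL
6	SSH
6	KJ
6	PL
6	SFHI
6	SH
6	KM1
7	UNK12
7	NMT5
8	UNK1
8	UNK2
8	UNK3
8	UNK4
8	UNK6
8	NMT1
9	TM
9	KMP2
9	NMT3
10	UNK10
10	JF
11	UNK9
11	ITO
12	BRW
12	HP
12	PRL
12	KH1
13	TS2
13	CHC
13	KC
13	KMM
13	KSE
13	KM3
13	UNK7
13	UNK8
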