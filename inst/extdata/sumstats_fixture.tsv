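SNP	CHR	BP	A1	A2	FREQ	BETA	SE	PVAL	N	INFO
rs1001	1	1000000	G	A	0.30	0.0500	0.0100	5.733031e-07	50000	0.95
rs1002	1	1250000	C	T	0.12	-0.0300	0.0120	1.241933e-02	50000	0.88
rs1003	2	2000000	A	T	0.45	0.0200	0.0090	2.626829e-02	50000	0.97
rs1004	2	2400000	T	C	0.05	0.0800	0.0200	6.334248e-05	50000	0.41
rs1005	3	3000000	G	T	0.25	0.0100	0.0110	3.633021e-01	50000	0.99
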