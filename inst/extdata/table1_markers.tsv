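gene_symbol	marked_cell_type	avg_count_tas1r3	avg_count_type3	log2fc	fdr
Plcb2	Tas1r3	5200	52.2	-14.4	1.10e-103
Tas1r2	Tas1r3	3103.2	0.1	-14.8	1.10e-26
Tas1r3	Tas1r3	6619.5	48.4	-6.7	1.58e-05
Tas1r1	Tas1r3	1804.5	14.8	-6.4	7.14e-04
Trpm5	Tas1r3	22979	1.5	-13.7	2.33e-62
P2rx7	Tas1r3	1624.7	30.8	-5.3	2.73e-03
Gna14	Tas1r3	22803	26.9	-9.1	1.37e-08
Gng13	Tas1r3	681.5	0.08	-12.3	8.42e-21
Chgb	TypeIII	1.5	8288.3	12.1	8.38e-38
Chga	TypeIII	4.7	8001.3	10.3	8.09e-21
Ncam1	TypeIII	30.4	16476.9	8.9	1.15e-26
Gad1	TypeIII	2.5	33978.7	13.5	1.90e-64
Car4	TypeIII	11.3	9307	9.2	1.57e-10
Pkd2l1	TypeIII	4.5	28791.2	12.6	7.70e-158
Pkd1l3	TypeIII	23	24051.7	9.8	4.24e-30
Snap25	TypeIII	70.5	73176.5	9.9	1.51e-50
Cacna2d1	TypeIII	11.5	26660.5	11.0	6.09e-42
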