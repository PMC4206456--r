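rsid	position_bp	allele0	allele1	chromosome	cm_position
rs1	1000	A	G	1	0.001
rs2	2000	C	T	1	0.002
rs3	3500	A	C	1	0.0035
rs4	5000	G	T	1	0.005
rs5	8000	A	T	1	0.008
rs6	12000	C	G	1	0.012
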