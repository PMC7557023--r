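# Private mitochondrial variants of a sequenced breed cohort, one row per
# carrier.  Read depths are synthetic (percent of 100 reads) reconstructing
# the reported per-carrier heteroplasmy percentages; sample ids are
# synthetic placeholders.
sample	pos	ref	alt	gene	depth_alt	depth_total
LB01	49	A	G	tRNA-Phe	96	100
LB02	1069	T	C	tRNA-Val	99	100
LB03	4764	T	C	ND2	100	100
LB04	5681	A	G	COX1	66	100
LB05	5681	A	G	COX1	89	100
LB06	11211	C	T	ND4	72	100
LB07	11211	C	T	ND4	66	100
LB08	13118	T	C	ND5	62	100
LB09	13544	A	G	ND5	100	100
LB10	13544	A	G	ND5	100	100
LB11	13544	A	G	ND5	100	100
LB12	13544	A	G	ND5	100	100
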