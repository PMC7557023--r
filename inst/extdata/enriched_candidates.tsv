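# Protein-changing variants in neuropathy candidate genes, with alternative
# allele frequencies in the sequenced cohort (39 dogs) and the 614 controls.
gene	chrom	pos	ref	alt	cdna	protein	consequence	aaf_cohort	aaf_controls
CNTNAP1	9	20294320	G	C	c.3863G>C	p.Arg1288Pro	missense	0.3974	0.0366
CNTNAP1	9	20298261	G	A	c.2585G>A	p.Gly862Glu	missense	0.1538	0.0067
DHTKD1	2	24316951	C	T	c.1820C>T	p.Ala607Val	missense	0.0897	0.0049
DIAPH3	22	15880854	G	A	c.2000G>A	p.Cys667Tyr	missense	0.1538	0.0689
DST	12	23771235	C	T	c.18224C>T	p.Thr6075Met	missense	0.0769	0.0008
DST	12	23782332	C	T	c.17800C>T	p.Arg5934Trp	missense	0.4359	0.0330
DST	12	23846624	C	T	c.10661C>T	p.Ser3554Leu	missense	0.0769	0.0369
DYNC1H1	8	70064306	C	T	c.13757C>T	p.Pro4586Leu	missense	0.1282	0.0051
GARS	14	43322005	G	A	c.622G>A	p.Val208Ile	missense	0.1154	0.0025
GJA9	15	3862761	G	C	c.344G>C	p.Arg115Thr	missense	0.5513	0.0868
JPH1	29	22710800	A	G	c.1531A>G	p.Ile511Val	missense	0.1923	0.0299
LOC477508	26	16348822	G	A	c.298G>A	p.Val100Met	missense	0.1795	0.0066
MME	23	49045461	A	T	c.1700A>T	p.Gln567Leu	missense	0.0769	0.0157
NEFH	26	22729485	G	A	c.1046G>A	p.Arg349His	missense	0.2821	0.0116
NEFH	26	22732974	NTGAAGGAGGAGGCCAAGTCCCCAG	N	c.1901_1924del	p.Val640_Pro647del	in-frame-del	0.3974	0.0849
NEFH	26	22733415	C	G	c.2326C>G	p.Pro768Ala	missense	0.0513	0.0059
OTOF	17	20534866	G	A	c.3451G>A	p.Ala1151Thr	missense	0.7051	0.0094
PDXK	31	37707445	G	C	c.774G>C	p.Arg258Ser	missense	0.1923	0.0898
PRX	1	113290407	G	A	c.784G>A	p.Ala262Thr	missense	0.1282	0.0257
SBF2	21	33036988	C	T	c.4114C>T	p.Pro1372Ser	missense	0.1667	0.0361
SLC12A6	30	853540	C	T	c.2498C>T	p.Ala833Val	missense	0.0513	0.0250
WNK1	27	42911057	C	G	c.7448C>G	p.Thr2483Arg	missense	0.0128	0.0058
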