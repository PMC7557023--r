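# Rare protein-changing variants private to the sequenced cohort of 39 dogs
# (absent from 614 control genomes).  alt_count is the alt-allele count out
# of 78 cohort chromosomes implied by the reported frequency.
gene	chrom	pos	ref	alt	cdna	protein	consequence	aaf_cohort	alt_count	aaf_controls
ATXN7	20	27234549	T	C	c.2285T>C	p.Val762Ala	missense	0.1154	9	0
CEP55	28	7777489	A	C	c.1334A>C	p.Tyr446Ser	missense	0.0256	2	0
CNTF	18	37758771	N	NINSA	c.401_402insA	p.Asn137fs	frameshift	0.0128	1	0
ELOVL4	12	40850011	NGGAGCACAGC	N	c.424_433delGGAGCACAGC	p.Gly142fs	frameshift	0.0128	1	0
FDX1L	20	50798661	N	NINS	c.124_125ins63	p.Thr41_Ala42ins	in-frame-ins	0.0128	1	0
GJA9	15	3863519	NGA	N	c.1108_1109delGA	p.Glu370fs	frameshift	0.0513	4	0
MCM3AP	31	39553337	NCTCTGAAGG	N	c.1785_1793delCTCTGAAGG	p.Ser596_Gly598del	in-frame-del	0.0128	1	0
NAPEPLD	18	16987520	G	C	c.559G>C	p.Ala187Pro	missense	0.1154	9	0
PLEKHG5	5	60325903	C	T	c.1585C>T	p.Gln529*	nonsense	0.0128	1	0
SPTBN4	1	113215064	N	NINS	c.1247_1248ins15	p.Ala416_Ala417ins	in-frame-ins	0.0128	1	0
SYNE1	1	42549994	C	T	c.17359C>T	p.Arg5788Trp	missense	0.0256	2	0
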