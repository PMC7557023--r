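# Illustrative haplogroup definition tree (generic labels, not a published
# nomenclature).  `variants` lists pos:alt tokens defining the node in
# addition to everything inherited from its ancestors.
label	parent	variants
HgA		
HgA1	HgA	100:G
HgA1a	HgA1	2500:T
HgA1b	HgA1	3100:C,4200:G
HgA1b1	HgA1b	5010:A
HgB	HgA	8000:A,9100:T
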