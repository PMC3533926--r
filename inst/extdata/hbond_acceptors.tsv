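resname	atom	note
*	O	protein backbone carbonyl
ASP	OD1	carboxylate
ASP	OD2	carboxylate
GLU	OE1	carboxylate
GLU	OE2	carboxylate
ASN	OD1	amide carbonyl
GLN	OE1	amide carbonyl
SER	OG	hydroxyl
THR	OG1	hydroxyl
TYR	OH	hydroxyl
HIS	ND1	imidazole
HIS	NE2	imidazole
HOH	O	water
DA	N1	adenine
DA	N3	adenine
DA	N7	adenine
DT	O2	thymine
DT	O4	thymine
DG	O6	guanine
DG	N3	guanine
DG	N7	guanine
DC	O2	cytosine
DC	N3	cytosine
ATP	N1	adenine
ATP	N3	adenine
ATP	N7	adenine
ATP	O1A	alpha phosphate
ATP	O2A	alpha phosphate
ATP	O1B	beta phosphate
ATP	O2B	beta phosphate
ATP	O1G	gamma phosphate
ATP	O2G	gamma phosphate
ATP	O3G	gamma phosphate
DA	OP1	phosphate
DA	OP2	phosphate
DT	OP1	phosphate
DT	OP2	phosphate
DG	OP1	phosphate
DG	OP2	phosphate
DC	OP1	phosphate
DC	OP2	phosphate
DA	O3'	sugar
DT	O3'	sugar
DG	O3'	sugar
DC	O3'	sugar
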