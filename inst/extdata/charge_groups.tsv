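resname	group	atom	sign
LYS	amine	NZ	1
ARG	guanidinium	NE	1
ARG	guanidinium	NH1	1
ARG	guanidinium	NH2	1
ASP	carboxylate	OD1	-1
ASP	carboxylate	OD2	-1
GLU	carboxylate	OE1	-1
GLU	carboxylate	OE2	-1
HIS	imidazolium	ND1	1
HIS	imidazolium	NE2	1
MG	ion	MG	2
ATP	phosphate	O1A	-1
ATP	phosphate	O2A	-1
ATP	phosphate	O1B	-1
ATP	phosphate	O2B	-1
ATP	phosphate	O1G	-1
ATP	phosphate	O2G	-1
ATP	phosphate	O3G	-1
DA	phosphate	OP1	-1
DA	phosphate	OP2	-1
DT	phosphate	OP1	-1
DT	phosphate	OP2	-1
DG	phosphate	OP1	-1
DG	phosphate	OP2	-1
DC	phosphate	OP1	-1
DC	phosphate	OP2	-1
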