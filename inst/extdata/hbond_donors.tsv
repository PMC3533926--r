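resname	atom	note
*	N	protein backbone amide
LYS	NZ	side-chain amine
ARG	NE	guanidinium
ARG	NH1	guanidinium
ARG	NH2	guanidinium
SER	OG	hydroxyl
THR	OG1	hydroxyl
TYR	OH	hydroxyl
ASN	ND2	amide
GLN	NE2	amide
HIS	ND1	imidazole
HIS	NE2	imidazole
TRP	NE1	indole
CYS	SG	thiol
HOH	O	water
DA	N6	adenine amine
DC	N4	cytosine amine
DG	N2	guanine amine
ATP	N6	adenine amine
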