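# Donor/acceptor chemistry per residue and nucleotide.
# resid "*" rows apply to any residue (backbone atoms).
# donor/acceptor are 0/1 flags for the named heavy atom.
resid	name	donor	acceptor
*	N	1	0
*	O	0	1
*	OXT	0	1
*	O1P	0	1
*	O2P	0	1
*	OP1	0	1
*	OP2	0	1
*	O3'	0	1
*	O5'	0	1
*	O4'	0	1
ARG	NE	1	0
ARG	NH1	1	0
ARG	NH2	1	0
LYS	NZ	1	0
SER	OG	1	1
THR	OG1	1	1
TYR	OH	1	1
ASN	ND2	1	0
ASN	OD1	0	1
GLN	NE2	1	0
GLN	OE1	0	1
ASP	OD1	0	1
ASP	OD2	0	1
GLU	OE1	0	1
GLU	OE2	0	1
HIS	ND1	1	1
HIS	NE2	1	1
HSD	ND1	1	1
HSD	NE2	1	1
TRP	NE1	1	0
CYS	SG	1	1
MET	SD	0	1
DA	N6	1	0
DA	N1	0	1
DA	N3	0	1
DA	N7	0	1
DG	N1	1	0
DG	N2	1	0
DG	O6	0	1
DG	N3	0	1
DG	N7	0	1
DC	N4	1	0
DC	O2	0	1
DC	N3	0	1
DT	N3	1	0
DT	O2	0	1
DT	O4	0	1
A	N6	1	0
A	N1	0	1
A	N3	0	1
A	N7	0	1
G	N1	1	0
G	N2	1	0
G	O6	0	1
G	N3	0	1
G	N7	0	1
C	N4	1	0
C	O2	0	1
C	N3	0	1
T	N3	1	0
T	O2	0	1
T	O4	0	1
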