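# Synthetic bead-name -> bead-type mapping for Martini-style CG proteins.
# Columns: resname  atom  type  charge (elementary charges).
# The backbone bead of every residue maps to P5; sidechain beads follow a
# reduced 13-type alphabet matching the bundled interaction tables.
ALA	BB	P5	0
ARG	BB	P5	0
ARG	SC1	N0	0
ARG	SC2	Qd	1
ASN	BB	P5	0
ASN	SC1	P5	0
ASP	BB	P5	0
ASP	SC1	Qa	-1
CYS	BB	P5	0
CYS	SC1	C5	0
GLN	BB	P5	0
GLN	SC1	P4	0
GLU	BB	P5	0
GLU	SC1	Qa	-1
GLY	BB	P5	0
HIS	BB	P5	0
HIS	SC1	C5	0
HIS	SC2	P1	0
HIS	SC3	P1	0
ILE	BB	P5	0
ILE	SC1	C1	0
LEU	BB	P5	0
LEU	SC1	C1	0
LYS	BB	P5	0
LYS	SC1	C3	0
LYS	SC2	Qd	1
MET	BB	P5	0
MET	SC1	C5	0
PHE	BB	P5	0
PHE	SC1	C5	0
PHE	SC2	C5	0
PHE	SC3	C5	0
PRO	BB	P5	0
PRO	SC1	C3	0
SER	BB	P5	0
SER	SC1	P1	0
THR	BB	P5	0
THR	SC1	P1	0
TRP	BB	P5	0
TRP	SC1	C5	0
TRP	SC2	C5	0
TRP	SC3	C5	0
TRP	SC4	P1	0
TYR	BB	P5	0
TYR	SC1	C5	0
TYR	SC2	C5	0
TYR	SC3	P1	0
VAL	BB	P5	0
VAL	SC1	C3	0
W	W	W	0
PGU	GN	Nda	0
PGU	GM	Nda	0
PGU	PS1	P5	0
PGU	PS2	Qa	-1
DUM	MB1	W	0
DUM	MB2	W	0
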