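residue_name	atom_name	charge	radius
ASP	OD1	-0.5	NA
ASP	OD2	-0.5	NA
GLU	OE1	-0.5	NA
GLU	OE2	-0.5	NA
LYS	NZ	1	NA
ARG	NH1	0.5	NA
ARG	NH2	0.5	NA
ALA	OXT	-1	NA
ARG	OXT	-1	NA
ASN	OXT	-1	NA
ASP	OXT	-1	NA
CYS	OXT	-1	NA
GLN	OXT	-1	NA
GLU	OXT	-1	NA
GLY	OXT	-1	NA
HIS	OXT	-1	NA
ILE	OXT	-1	NA
LEU	OXT	-1	NA
LYS	OXT	-1	NA
MET	OXT	-1	NA
PHE	OXT	-1	NA
PRO	OXT	-1	NA
SER	OXT	-1	NA
THR	OXT	-1	NA
TRP	OXT	-1	NA
TYR	OXT	-1	NA
VAL	OXT	-1	NA
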