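# Extended Ala-X-Ala tripeptide accessible surface areas, version axa-1.0
# Reference per-residue ASA in Angstrom^2 for the fully extended state,
# used to normalise absolute ASA into relative ASA (percent).
# Values follow the Ala-X-Ala scale of Ahmad et al. (2004).
residue	asa_A2
ALA	110.2
ARG	229.0
ASN	146.4
ASP	144.1
CYS	140.4
GLN	178.6
GLU	174.7
GLY	78.7
HIS	181.9
ILE	185.0
LEU	183.0
LYS	205.7
MET	200.1
PHE	200.7
PRO	142.0
SER	117.2
THR	138.7
TRP	259.2
TYR	229.1
VAL	153.7
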