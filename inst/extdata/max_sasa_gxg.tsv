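# Maximum solvent accessible surface area of residue X in an ideal-geometry
# extended Gly-X-Gly tripeptide, Angstrom^2 (heavy atoms, Bondi radii,
# probe 1.4 A, 960-point deterministic lattice).  Computed with this
# package as the maximum over its rotamer library; regenerate with
# fepscout::compute_reference_sasa().
aa3	max_sasa
ALA	113.23
ARG	252.09
ASN	170.04
ASP	167.42
CYS	150.08
GLN	202.86
GLU	201.00
GLY	86.43
HIS	202.80
ILE	187.60
LEU	189.86
LYS	217.15
MET	207.37
PHE	222.39
PRO	138.64
SER	131.35
THR	155.08
TRP	267.33
TYR	240.67
VAL	163.07
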