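# Curated example set: interface point mutations in three protease-
# inhibitor / antibody-antigen benchmark complexes where a carboxylate
# side chain is modelled in a nonstandard (neutral) protonation state.
# ddg_* columns are per-state predicted changes in binding free energy
# (kcal/mol) from alchemical FEP, with the state penalty already folded
# in (penalty_included = TRUE).  role says which end state carries the
# acid; fsasa_pct is the wild-type residue's integer-percent fractional
# SASA in the bound input structure.
system	chain	resnum	wt	mt	fsasa_pct	role	complex_state	unbound_state	comment	ddg_protonated	ddg_charged	penalty_included
1BRS	A	73	E	Q	1	wild_type	GLH	GLH	hydrogen bond with adjacent carboxylate on same chain	1.27	-8.45	TRUE
1BRS	A	73	E	C	1	wild_type	GLH	GLH	hydrogen bond with adjacent carboxylate on same chain	0.96	-3.23	TRUE
1BRS	A	73	E	S	1	wild_type	GLH	GLH	hydrogen bond with adjacent carboxylate on same chain	2.92	-2.86	TRUE
1BRS	A	73	E	A	1	wild_type	GLH	GLH	hydrogen bond with adjacent carboxylate on same chain	0.60	-10.02	TRUE
1BRS	A	102	H	D	0	mutant	ASH	ASH	mutant close to buried carboxylate; stabilising hydrogen bond	3.23	28.89	TRUE
1BRS	D	35	D	A	1	wild_type	ASH	ASH	fully buried	2.24	0.73	TRUE
1R0R	I	15	A	D	0	mutant	ASH	ASP	buried in mostly hydrophobic receptor pocket in bound state	5.66	18.03	TRUE
1R0R	I	15	A	E	0	mutant	GLH	GLU	buried in mostly hydrophobic receptor pocket in bound state	6.35	13.34	TRUE
1R0R	I	18	L	D	5	mutant	ASH	ASP	buried in mostly hydrophobic receptor pocket in bound state	4.89	11.36	TRUE
1R0R	I	18	L	E	5	mutant	GLH	GLU	buried in mostly hydrophobic receptor pocket in bound state	1.49	5.58	TRUE
3SGB	I	17	T	D	12	mutant	ASH	ASP	buried in mostly hydrophobic receptor pocket in bound state	3.88	7.81	TRUE
3SGB	I	17	T	E	12	mutant	GLH	GLU	buried in mostly hydrophobic receptor pocket in bound state	4.39	5.38	TRUE
3SGB	I	18	L	D	1	mutant	ASH	ASP	buried in mostly hydrophobic receptor pocket in bound state	6.70	15.13	TRUE
3SGB	I	18	L	E	1	mutant	GLH	GLU	buried in mostly hydrophobic receptor pocket in bound state	3.70	11.40	TRUE
VRC01	L	96	E	A	2	wild_type	GLH	GLH	caged by aromatics on antibody light chain	1.11	-0.49	TRUE
VRC03	L	96	E	A	1	wild_type	GLH	GLH	caged by aromatics on antibody light chain	1.77	-1.13	TRUE
VRCPG-04	L	96	E	A	3	wild_type	GLH	GLH	caged by aromatics on antibody light chain	-0.84	-0.74	TRUE
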