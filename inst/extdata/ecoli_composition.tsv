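# Macromolecular composition of exponentially growing E. coli and the
# precursor stoichiometry used to build the biosynthetic load vector.
# mass_fraction: g per g dry cell; residue_mass: g per mmol of monomer residue;
# precursors: mol precursor per mol residue (semicolon-separated id:coeff).
# The aggregate per-gram precursor demands reproduce the classic textbook
# values (e.g. R5P 0.90, 3PG 1.50, OAA 1.79, PYR 2.83 mmol per g cell).
# NADH coefficients are negative where biosynthesis nets NADH production.
# DNA row: 50% GC; purine dNTP = R5P + 3PG (aspartate N returns as fumarate,
# no net OAA); pyrimidine dNTP = R5P + OAA; NADPH covers ribonucleotide
# reduction. atp_per_bond: ATP per polymerized bond (DNA about one third of
# protein); atp_per_denovo applies to de novo dNTP synthesis only.
macromolecule	mass_fraction	residue_mass	precursors	atp_per_bond	atp_per_denovo
protein	0.550	0.1089	PYR:0.5609;PG3:0.2233;OAA:0.2809;PEP:0.1027;E4P:0.0715;R5P:0.0321;ACCOA:0.3460;AKG:0.2136;NADPH:2.83;NADH:-0.702	4.3	0
rna	0.205	0.3225	R5P:1;PG3:0.5;OAA:0.5;NADPH:0.1	2.4	0
dna	0.031	0.30895	R5P:1;PG3:0.5;OAA:0.5;NADPH:1.0	1.4	10
lipid	0.091	0.7050	GAP:1;ACCOA:15.5;NADPH:28	1.0	0
other	0.123	0.3000	G6P:0.5;F6P:0.173;NADPH:0.3	2.0	0
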