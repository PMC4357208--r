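# Metabolite registry for the bundled central-metabolism network.
# balanced = TRUE rows enter the stoichiometric matrix (mass-balanced pools);
# external species (glucose, excreted byproducts, CO2) are unbalanced.
# Several pools are lumped to the granularity of the published flux map:
# F6P includes FBP; GAP includes DHAP; PG3 includes 1,3-BPG/3PG/2PG;
# R5P is the pentose-phosphate pool (Ru5P/R5P/X5P); MAL includes fumarate
# and succinate downstream of the alpha-ketoglutarate dehydrogenase lump.
# carbons is the carbon count used for per-reaction carbon-balance checks
# (0 for redox cofactors, which carry no carbon in this representation).
id	name	balanced	carbons
GLC	glucose	FALSE	6
G6P	glucose-6-phosphate	TRUE	6
F6P	fructose-6-phosphate	TRUE	6
GAP	glyceraldehyde-3-phosphate	TRUE	3
PG3	3-phosphoglycerate	TRUE	3
PEP	phosphoenolpyruvate	TRUE	3
PYR	pyruvate	TRUE	3
ACCOA	acetyl-CoA (acetyl moiety)	TRUE	2
R5P	pentose-5-phosphate pool	TRUE	5
S7P	sedoheptulose-7-phosphate	TRUE	7
E4P	erythrose-4-phosphate	TRUE	4
OAA	oxaloacetate	TRUE	4
MAL	malate	TRUE	4
AKG	alpha-ketoglutarate	TRUE	5
ACEX	acetate (excreted)	FALSE	2
LACX	lactate (excreted)	FALSE	3
CO2	carbon dioxide	FALSE	1
NADH	NADH	TRUE	0
NADPH	NADPH	TRUE	0
FADH2	FADH2	TRUE	0
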