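# Central-metabolism network of E. coli at the granularity of the published
# flux map: glycolysis, hexose monophosphate (HMP) pathway with transketolase/
# transaldolase, TCA cycle split at alpha-ketoglutarate and malate (so that the
# AKG biosynthetic drain and the malic enzyme branch are representable),
# PTS-coupled glucose uptake (PEP -> PYR during import), anaplerotic PEP
# carboxylation, acetate/lactate excretion, and respiration sinks for NADH and
# FADH2 (ATP credited at the configured P/O ratios at run time, not here).
# Cofactor columns are per unit flux; CO2 is the signed net CO2 release.
# Isocitrate dehydrogenase is NADP-linked, so one NADPH per r_TCA.
id	equation	reversible	ATP	NADH	NADPH	FADH2	CO2
r_GLU	GLC + PEP -> G6P + PYR	FALSE	0	0	0	0	0
r_PGI	G6P -> F6P	TRUE	0	0	0	0	0
r_HMP	G6P -> R5P	FALSE	0	0	2	0	1
r_TK1	2 R5P -> S7P + GAP	FALSE	0	0	0	0	0
r_TA	S7P + GAP -> E4P + F6P	FALSE	0	0	0	0	0
r_TK2	R5P + E4P -> F6P + GAP	FALSE	0	0	0	0	0
r_PFK	F6P -> 2 GAP	FALSE	-1	0	0	0	0
r_GAPD	GAP -> PG3	FALSE	1	1	0	0	0
r_ENO	PG3 -> PEP	TRUE	0	0	0	0	0
r_PYK	PEP -> PYR	FALSE	1	0	0	0	0
r_PDH	PYR -> ACCOA	FALSE	0	1	0	0	1
r_ANA	PEP -> OAA	FALSE	0	0	0	0	-1
r_TCA	ACCOA + OAA -> AKG	FALSE	0	0	1	0	1
r_OGDH	AKG -> MAL	FALSE	1	1	0	1	1
r_MDH	MAL -> OAA	TRUE	0	1	0	0	0
r_ME	MAL -> PYR	FALSE	0	0	1	0	1
r_ACE	ACCOA -> ACEX	FALSE	1	0	0	0	0
r_LAC	PYR -> LACX	FALSE	0	-1	0	0	0
r_RESPN	-	FALSE	0	-1	0	0	0
r_RESPF	-	FALSE	0	0	0	-1	0
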