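# Published flux-scenario table (five extreme scenarios of the tight-acetate
# problem; fluxes in mmol per g cell h, yields Y_xs in g cell/g glucose and
# Y_xatp in g cell/mol ATP), transcribed from the source table's run-together
# digit strings using the column template of scenario 1.
# Parse notes:
#  * scenarios 1 and 5 print ten tokens for eleven columns; the missing cell
#    is r_ME = 0, identified from the oxaloacetate/malate balance invariant
#    r_ANA - r_ME = 0.57 that every unambiguous row satisfies;
#  * scenario 2's r_ANA is read as 1.2 (the alternative reading 1.24 would
#    leave r_CO2 = 0.12, inconsistent with carbon bookkeeping);
#  * co_optimal lists the additional objectives the source annotates on each
#    row ("r4"/"r5" are read as the two transketolase fluxes);
#  * values are printed to 2 significant figures; Y_xatp = 10 and 7.0
#    correspond to the ATP production bounds 20 and 28.571 mmol/g h.
scenario	objective	co_optimal	Y_xs	Y_xatp	r_TCA	r_PYK	r_HMP	r_ME	r_TA	r_TK1	r_TK2	r_ANA	r_CO2
1	MIN r_TCA	MIN r_GLU;MIN r_ME;MAX r_HMP;MAX r_TA;MAX r_TK1;MAX r_TK2	0.45	10	0.60	0.48	1.40	0	0.43	0.43	0.36	0.57	4.64
2	MIN r_PYK	-	0.44	10	0.77	0	0.99	0.63	0.29	0.29	0.22	1.2	4.12
3	MAX r_ME	MAX r_ANA;MIN r_HMP;MIN r_TA;MIN r_TK1;MIN r_TK2	0.40	7.3	1.6	0	0.32	1.15	0.072	0.072	0	1.7	5.38
4	MAX r_TCA	MAX r_GLU	0.39	7.0	1.7	0.13	0.32	1.1	0.072	0.072	0	1.6	5.72
5	MAX r_PYK	MIN r_ANA	0.39	7.0	1.4	0.93	1.00	0	0.30	0.30	0.23	0.57	6.59
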