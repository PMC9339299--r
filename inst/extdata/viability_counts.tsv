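# tetradkit bundled data: sporulation efficiency and spore-viability class
# counts per strain, plus chromosome III meiosis-I nondisjunction events
# scored as double-nonmater tetrads among the 2-spore-viable class
# (NA = not determined).
strain	sporulation_pct	n_cells	n4	n3	n2	n1	n0	ndj_events	ndj_examined	pct_viability_printed	ndj_pct_printed
wild_type	50	6800	503	64	15	2	0	0	15	96	NA
htz1	48	6841	320	251	102	48	60	1	102	73	0.98
hho1	56	6795	533	64	41	5	0	NA	NA	94	NA
htz1_hho1	48	2601	415	284	127	35	8	1	127	81	0.79
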