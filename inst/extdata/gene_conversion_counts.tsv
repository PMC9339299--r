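# tetradkit bundled data: gene-conversion tallies over 4-spore-viable
# tetrads per strain, with the values printed alongside them in the source
# tabulation (percent of tetrads with >=1 conversion, conversions per
# tetrad, ratio versus wild type, per-chromosome split of all conversions,
# and the p-values of the printed comparisons against wild type).
strain	n_tetrads	n_with_gc	total_gc	pct_with_gc_printed	gc_per_tetrad_printed	ratio_vs_wt_printed	pct_gc_III_printed	pct_gc_VIII_printed	p_two_prop_printed	p_gc_rate_printed	p_fisher_printed
wild_type	497	42	63	8	0.13	1	44	56	NA	NA	NA
htz1	314	34	42	11	0.13	1	36	64	0.26	0.77	0.2675
hho1	530	64	91	12	0.17	1.3	45	55	0.056	0.044	0.0645
htz1_hho1	396	68	150	17	0.38	2.9	75	25	0.0001	0.0001	0.0001
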