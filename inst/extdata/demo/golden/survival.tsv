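contrast	hazard_ratio	ci_low	ci_high	log2_hr	p_value	infinite	logrank_chisq	logrank_p	n	n_events
P+G+ vs P+G-	3.250907909	0.3717756839	28.42682481	1.700842688	0.2865908669	FALSE	1.264173326	0.2608626128	10	7
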