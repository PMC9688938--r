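metric_x	metric_y	n_total	n_significant	n_positive	n_negative	positive_fraction	r_threshold	p_threshold
NES:PDL1_SIG	NES:MES	2	1	1	0	1	0.3	0.05
NES:PDL1_SIG	NES:EPI	2	2	0	2	0	0.3	0.05
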