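dataset_id	metric_x	metric_y	rho	p_value	n_samples	undefined	p_bh	significant	direction
d1	NES:PDL1_SIG	NES:EPI	-0.7969924812	2.591747429e-05	20	FALSE	5.183494859e-05	TRUE	negative
d2	NES:PDL1_SIG	NES:EPI	-0.7082706767	0.0004746151083	20	FALSE	0.0004746151083	TRUE	negative
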