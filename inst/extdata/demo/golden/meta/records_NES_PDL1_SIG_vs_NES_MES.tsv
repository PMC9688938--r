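dataset_id	metric_x	metric_y	rho	p_value	n_samples	undefined	p_bh	significant	direction
d1	NES:PDL1_SIG	NES:MES	0.5172932331	0.01950054706	20	FALSE	0.03900109412	TRUE	positive
d2	NES:PDL1_SIG	NES:MES	0.4270676692	0.0603760476	20	FALSE	0.0603760476	FALSE	ns
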