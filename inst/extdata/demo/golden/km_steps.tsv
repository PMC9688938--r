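group	time	n_risk	n_event	estimate	std_error
P+G-	13.8	3	0	1	0
P+G-	60.422	2	1	0.5	0.3535533906
P+G-	93.161	1	1	0	NaN
P+G+	10.359	7	1	0.8571428571	0.1322600143
P+G+	17.74	6	0	0.8571428571	0.1322600143
P+G+	23.101	5	1	0.6857142857	0.1862942279
P+G+	52.368	4	0	0.6857142857	0.1862942279
P+G+	56.209	3	1	0.4571428571	0.2241754138
P+G+	61.338	2	1	0.2285714286	0.1966878314
P+G+	74.708	1	1	0	NaN
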