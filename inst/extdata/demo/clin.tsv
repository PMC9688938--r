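sample_id	os_time	os_event
P01	93.161	1
P02	66.915	1
P03	21.963	1
P04	47.995	1
P05	29.937	1
P06	19.516	1
P07	80.819	1
P08	7.187	1
P09	13.8	0
P10	153.395	1
P11	61.338	1
P12	23.101	1
P13	10.359	1
P14	65.469	1
P15	52.368	0
P16	60.422	1
P17	74.708	1
P18	56.209	1
P19	300.953	0
P20	17.74	0
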