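sample_id	NES:PDL1_SIG	NES:MES	NES:EPI	NES:GLYCOLYSIS	EXPR:CD274
P01	-0.3626684642	-0.415635005	0.4806816807	0.3091157262	4.10947114
P02	-0.02178552614	-0.4024563023	0.5001779902	0.1993950046	5.449356388
P03	-0.254678737	-0.3665324202	0.5050863756	0.1266619796	3.97953123
P04	-0.1786113645	-0.3201116305	0.509300154	0.08983103413	5.704401171
P05	-0.3958942507	-0.3301685473	0.487798099	0.115679385	4.470263922
P06	-0.2698475035	-0.3392829621	0.517609079	-0.06413611003	4.128857865
P07	-0.2236323504	-0.4081708405	0.4705796829	0.3533434988	4.004902382
P08	-0.1112895785	-0.2724744711	0.5197091661	-0.4279690642	4.073786209
P09	-0.381034746	-0.2338919989	0.5110946231	0.02486859843	5.738551061
P10	0.4717687683	-0.4727922315	0.3844814135	-0.04674592908	7.522148569
P11	0.6041057493	0.3108208115	-0.4473739752	0.1817711737	7.5778752
P12	0.4569471105	0.2425204593	-0.4713117669	0.4883104724	9.223158897
P13	0.2020219671	0.437581706	-0.3287354854	0.1961584545	8.418556093
P14	-0.004024337148	0.3481155358	-0.3573819231	0.5720309358	6.929505274
P15	0.4278167433	0.4477652731	-0.4721542004	0.1707251586	8.423548883
P16	0.446937565	0.2981013745	-0.4249017072	0.4052332043	8.734006024
P17	0.4001827096	0.4737696433	-0.4671704284	0.1756448465	6.55259207
P18	0.4214919297	0.3154270659	-0.3775246774	0.355451153	7.385642299
P19	0.1258708466	0.5272077685	-0.4730083121	0.1503317591	5.532656444
P20	0.3379203718	0.4662240414	-0.4802908339	0.1442089973	7.152524036
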