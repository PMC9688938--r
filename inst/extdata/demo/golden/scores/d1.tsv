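sample_id	NES:PDL1_SIG	NES:MES	NES:EPI	NES:GLYCOLYSIS	EXPR:CD274
P01	-0.2359118856	-0.3037027165	0.5154218866	0.01778409897	5.931894394
P02	-0.06543867743	-0.4337056452	0.4948004176	0.1879603312	4.837301368
P03	-0.1778173264	-0.2181365542	0.5124144718	-0.4959494486	3.659225644
P04	-0.3767634478	-0.1886120918	0.5007860131	-0.2839070592	3.791858689
P05	0.1425602527	-0.40697362	0.4956193919	-0.2549387104	5.923930976
P06	-0.4607938591	-0.1158668106	0.4572742729	-0.1460426182	3.594710662
P07	-0.2072865826	-0.2909188058	0.4186893563	0.1562112411	4.898065142
P08	-0.1964564615	-0.2693548048	0.5148803881	-0.1287266889	3.915892762
P09	0.09980559176	-0.2705807848	0.4334917558	-0.08892693683	5.981034173
P10	-0.1181837951	-0.1887186244	0.5022749776	-0.3245163026	5.698548744
P11	0.5011693151	0.5550581037	-0.4726402944	0.0388136553	7.69041771
P12	0.4806644784	0.3964617172	-0.3702623862	0.1798972017	7.344207064
P13	0.4930580912	0.3708462034	-0.4845781134	0.385943497	8.970134117
P14	-0.05268412706	0.4882142739	-0.02386902553	-0.4173052931	4.248546797
P15	0.5392061409	0.3012995696	-0.4127526382	0.3876589209	9.7603628
P16	0.3942449071	0.5662943548	-0.2646254442	-0.04559293521	6.4501949
P17	0.3864289642	0.4795544958	-0.3562835414	0.1608300893	7.160429681
P18	0.3837564168	0.3364743587	-0.4248560416	0.5040505514	8.453492106
P19	-0.1413195862	0.5329461183	-0.2040923829	0.3641839343	5.773813352
P20	0.4193005229	0.3392326316	-0.1784948958	0.1925612513	7.049070887
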