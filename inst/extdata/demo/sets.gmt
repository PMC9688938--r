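EPI	na	CDH1	EGENE01	EGENE02	EGENE03	EGENE04	EGENE05	EGENE06	EGENE07	EGENE08	EGENE09	EGENE10	EGENE11	EGENE12	EGENE13	EGENE14	EGENE15	EGENE16	EGENE17	EGENE18	EGENE19
MES	na	MGENE01	MGENE02	MGENE03	MGENE04	MGENE05	MGENE06	MGENE07	MGENE08	MGENE09	MGENE10	MGENE11	MGENE12	MGENE13	MGENE14	MGENE15	MGENE16	MGENE17	MGENE18	MGENE19	MGENE20
PDL1_SIG	na	CD274	PGENE01	PGENE02	PGENE03	PGENE04	PGENE05	PGENE06	PGENE07	PGENE08	PGENE09	PGENE10	PGENE11	PGENE12	PGENE13	PGENE14	PGENE15	PGENE16	PGENE17	PGENE18	PGENE19
GLYCOLYSIS	na	GGENE01	GGENE02	GGENE03	GGENE04	GGENE05	GGENE06	GGENE07	GGENE08	GGENE09	GGENE10	GGENE11	GGENE12	GGENE13	GGENE14	GGENE15	GGENE16	GGENE17	GGENE18	GGENE19	GGENE20
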