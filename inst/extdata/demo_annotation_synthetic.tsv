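accession	categories
MYH7	structural/contractile
MYH1	structural/contractile
MYH2	structural/contractile
MYH4	structural/contractile
P0001	mitochondrion
P0002	mitochondrion
P0003	mitochondrion;TCA cycle
P0004	mitochondrion;TCA cycle
P0005	mitochondrion
P0006	TCA cycle
P0007	spliceosome
P0008	spliceosome
P0009	spliceosome
P0010	immune
P0011	immune
P0012	proteostasis
P0013	proteostasis
P0014	DNA damage/repair
P0015	DNA damage/repair
P0016	senescence
P0017	apoptosis
P0018	autophagy
P0019	transcription regulation
P0020	structural/contractile
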