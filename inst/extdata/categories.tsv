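category	description
mitochondrion	mitochondrial structural proteins and enzymes
TCA cycle	tricarboxylic acid cycle enzymes
structural/contractile	sarcomeric, cytoskeletal and contractile proteins
spliceosome	spliceosome complex and splicing regulation
transcription regulation	transcription factors and co-regulators
immune	innate and adaptive immune proteins, complement, inflammation
apoptosis	pro- and anti-apoptotic regulators
DNA damage/repair	DNA damage response and repair proteins
senescence	senescence-associated proteins
proteostasis	chaperones, co-chaperones, heat-shock proteins
autophagy	autophagy and lysosomal proteins
other	uncategorized proteins
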