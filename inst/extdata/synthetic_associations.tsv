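disease	microbe
asthma	Proteobacteria
asthma	Firmicutes
asthma	Clostridium_difficile
asthma	Prevotella
IBD	Proteobacteria
IBD	Bacteroidetes
IBD	Prevotella
IBD	Lactobacillus
obesity	Firmicutes
obesity	Bacteroidetes
obesity	Lactobacillus
obesity	Bifidobacterium
type_2_diabetes	Bifidobacterium
type_2_diabetes	Lactobacillus
type_2_diabetes	Proteobacteria
psoriasis	Streptococcus
psoriasis	Staphylococcus_aureus
periodontitis	Streptococcus
periodontitis	Prevotella
periodontitis	Haemophilus
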