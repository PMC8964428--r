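drug	pns	cns	pathway	cancer	ps_decimals
lycorine	-1.96614484	1.2588	Basal_Transcription_Factors	BRCA	6
podophyllotoxin	-1.8677839	1.2588	Basal_Transcription_Factors	BRCA	6
cephaeline	-1.486685	1.2588	Basal_Transcription_Factors	BRCA	6
cephaeline	-1.31212566	1.0742	Cytosolic_Dna_Sensing_Pathway	BRCA	6
emetine	-1.292820115	1.0742	Cytosolic_Dna_Sensing_Pathway	BRCA	5
thapsigargin	2.0442182667	-1.4763	Arachidonic_Acid_Metabolism	BRCA	5
esculetin	1.8627699667	-1.4763	Arachidonic_Acid_Metabolism	BRCA	5
demecolcine	1.7208179	-1.5188	Jak_Stat_Signaling_Pathway	BRCA	5
thapsigargin	1.6467795333	-1.5188	Jak_Stat_Signaling_Pathway	BRCA	5
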