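# Rich-club node set: bilateral precuneus, superior frontal and superior
# parietal cortices, hippocampus, putamen and thalamus. Editable; one AAL
# region label per line.
Frontal_Sup_L
Frontal_Sup_R
Parietal_Sup_L
Parietal_Sup_R
Precuneus_L
Precuneus_R
Hippocampus_L
Hippocampus_R
Putamen_L
Putamen_R
Thalamus_L
Thalamus_R
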