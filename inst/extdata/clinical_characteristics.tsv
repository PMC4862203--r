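cohort	characteristic	category	count
Clinseq	histologic_grade	grade1	39
Clinseq	histologic_grade	grade2	121
Clinseq	histologic_grade	grade3	115
TCGA	histologic_grade	grade1	64
TCGA	histologic_grade	grade2	228
TCGA	histologic_grade	grade3	195
Clinseq	tumour_size	ge20mm	150
Clinseq	tumour_size	lt20mm	125
TCGA	tumour_size	ge20mm	317
TCGA	tumour_size	lt20mm	170
TCGA	lymph_node	positive	260
TCGA	lymph_node	negative	227
Clinseq	er_status	positive	231
Clinseq	er_status	negative	42
Clinseq	er_status	missing	2
TCGA	er_status	positive	384
TCGA	er_status	negative	102
TCGA	er_status	missing	1
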