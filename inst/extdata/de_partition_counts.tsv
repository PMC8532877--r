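metric	count
deg_up	84
deg_down	147
deg_total	231
deg_novel	45
dei_up	534
dei_down	639
dei_total	1173
dei_novel	642
iso_shared	11422
iso_pacbio_only	34152
iso_illumina_only	7554
iso_union	53128
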