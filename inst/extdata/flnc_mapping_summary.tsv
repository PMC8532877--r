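category	pre_correction	post_correction	merge
unmapped	2645	1159	1144
multiple_best	1467	1506	1333
low_pid	14116	11041	9935
high_quality	207181	211703	212997
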