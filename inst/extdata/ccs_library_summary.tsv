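library	ccs	five_prime_reads	three_prime_reads	polya_reads	filtered_short	non_full_length	full_length	flnc	mean_flnc_length
1-2kb	144625	100807	105218	102657	10454	46175	87996	87230	1592
2-3kb	133687	90964	95303	93083	3043	50806	79838	77147	2604
3-6kb	135310	79482	84285	80576	6894	60436	67980	61032	2523
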