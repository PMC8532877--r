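bin	refseq	pacbio
<1K	4284	1214
1-2K	5770	3254
2-3K	4401	4637
>=3K	8115	9386
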