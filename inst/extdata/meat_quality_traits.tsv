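trait	mean_ld	sem_ld	n_ld	mean_bf	sem_bf	n_bf	printed_p
pH45min	6.71	0.13	4	6.94	0.13	4	0.26
pH24h	5.72	0.06	4	5.83	0.08	4	0.28
lightness_L	35.35	1.59	4	35.23	1.46	4	0.96
redness_a	11.63	0.75	4	14.08	0.41	4	0.03
yellowness_b	1.28	0.43	4	0.53	0.37	4	0.23
water_loss_pct	33.02	2.12	4	28.14	5.22	4	0.42
water_hold_pct	48.44	1.98	4	46.33	0.75	4	0.32
shear_force_N	29.06	2.54	4	48.65	7.20	4	0.04
marbling_score	6.00	0.00	4	5.25	0.25	4	0.02
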