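dataset	dataset_size	nnz	nonneg_ratio_pct	sparsity_pct	rows	rows_over_cols_pct	file_size_k	l1_norm	l2_norm	rank
acute_myelogenous_leukemia	2316639	81104	48.12	3.50	191	1.574738	92	34	143.673	157
thyroid_carcinoma	6015984	189060	58.81	3.14	496	4.089373	175	92	224.882	279
prostate_cancer	4038957	556304	38.74	13.77	333	2.745486	812	259	372.086	325
colorectal_cancer	3117153	753833	54.11	24.18	257	2.118889	910	224	492.879	253
bladder_cancer	1552512	780530	53.59	50.28	128	1.055322	800	144	435.185	127
clear_cell_carcinoma_of_kidney	5288244	1196243	50.32	22.62	436	3.59469	1489	420	653.243	433
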