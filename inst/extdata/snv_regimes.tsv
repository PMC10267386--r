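dataset	dataset_size	nnz	sparsity_pct	rows	rows_over_cols_pct	file_size_k	l1_norm	l2_norm	rank
brain_tumor	1006707	395	0.039	83	0.684	2	38	10.167	66
acute_myelogenous_leukemia	2377284	1683	0.071	196	1.616	7	56	11.417	187
thyroid_carcinoma	4863729	4780	0.098	401	3.306	17	241	16.173	400
prostate_cancer	4038957	9004	0.223	333	2.745	27	52	29.835	332
ovarian_cancer	3832764	12873	0.336	316	2.605	35	312	22.599	316
breast_cancer	6202131	20287	0.327	507	4.145	52	208	24.876	507
bladder_cancer	1576770	25368	1.609	130	1.072	53	167	52.160	130
clear_cell_carcinoma_of_kidney	5142696	24023	0.470	424	3.496	60	274	30.251	424
colorectal_cancer	2716896	48038	1.768	224	1.847	91	415	294.987	224
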