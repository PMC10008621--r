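section	name	a	b	c	d
design	median_control	9.5	NA	NA	NA
design	median_experimental	16	NA	NA	NA
design	alpha_one_sided	0.05	NA	NA	NA
design	power	0.8	NA	NA	NA
design	accrual_months	24	NA	NA	NA
design	total_months	48	NA	NA	NA
response	PR	11	NA	NA	NA
response	SD	14	NA	NA	NA
response	PD	5	NA	NA	NA
table2x2	atm_mutation	3	8	0	19
table2x2	hrr_pathway	7	2	4	17
table2x2	chromatin_remodeling	7	4	4	15
table2x2	mast_cell_score_high	2	12	8	6
table2x2	effector_t_cell_3gene_high	9	5	1	13
table2x2	cea_abnormal	1	8	10	11
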