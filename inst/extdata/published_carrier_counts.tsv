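category	exposed_carriers	exposed_n	unexposed_carriers	unexposed_n	printed_pct_exposed	printed_pct_unexposed
monosomies	32	34	13	34	94.1	38.2
trisomies	26	34	3	34	76.4	8.8
scas	27	34	8	34	79.4	23.5
chtb_chrb	25	34	14	34	73.5	41.1
fra_other	16	34	10	34	47.1	29.4
fra_9q12	32	34	17	34	94.1	50
cv_1qh	20	34	4	34	58.8	11.8
cv_9qh	8	34	4	34	23.5	11.8
cv_inv9	7	34	1	34	20.5	2.9
cv_16qh	9	34	0	34	26.4	0
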