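sample	chrom	start	end	call	mean_logr	mcf	n_probes	n_het	band_lower	band_upper
CDKN2A_P15	7	1	64999999	neutral	0.001	NA	1300	390	0.5	0.5
CDKN2A_P15	7	65000000	110000000	loss	-0.98	0.99	900	270	0.01	0.99
CDKN2A_P15	7	110000001	159000000	neutral	-0.002	NA	980	294	0.5	0.5
CDKN2A_P15	9	1	20000000	gain	0.57	0.98	400	120	0.34	0.66
CDKN2A_P15	9	20000001	138000000	neutral	0.003	NA	2360	708	0.5	0.5
CDKN2A_P30	7	1	64999999	neutral	-0.001	NA	1300	390	0.5	0.5
CDKN2A_P30	7	65000000	110000000	loss	-0.97	0.98	900	270	0.01	0.99
CDKN2A_P30	7	110000001	159000000	neutral	0.002	NA	980	294	0.5	0.5
CDKN2A_P30	9	1	20000000	gain	0.58	0.99	400	120	0.33	0.67
CDKN2A_P30	9	20000001	138000000	neutral	0.001	NA	2360	708	0.5	0.5
CDKN2A_P45	7	1	64999999	neutral	0.002	NA	1300	390	0.5	0.5
CDKN2A_P45	7	65000000	110000000	loss	-0.99	1.0	900	270	0.0	1.0
CDKN2A_P45	7	110000001	159000000	neutral	-0.001	NA	980	294	0.5	0.5
CDKN2A_P45	9	1	20000000	gain	0.59	1.0	400	120	0.33	0.67
CDKN2A_P45	9	20000001	138000000	neutral	-0.002	NA	2360	708	0.5	0.5
RB1_P15	3	1	149999999	neutral	0.001	NA	3000	900	0.5	0.5
RB1_P15	3	150000000	160000000	loss	-0.96	0.98	200	60	0.02	0.98
RB1_P15	3	160000001	198000000	neutral	0.002	NA	760	228	0.5	0.5
RB1_P15	16	1	64999999	neutral	-0.001	NA	1300	390	0.5	0.5
RB1_P15	16	65000000	80000000	gain	0.57	0.97	300	90	0.34	0.66
RB1_P15	16	80000001	90000000	neutral	0.001	NA	200	60	0.5	0.5
RB1_P30	3	1	149999999	neutral	-0.002	NA	3000	900	0.5	0.5
RB1_P30	3	150000000	160000000	loss	-0.98	0.99	200	60	0.01	0.99
RB1_P30	3	160000001	198000000	neutral	0.001	NA	760	228	0.5	0.5
RB1_P30	16	1	64999999	neutral	0.002	NA	1300	390	0.5	0.5
RB1_P30	16	65000000	80000000	gain	0.58	0.99	300	90	0.33	0.67
RB1_P30	16	80000001	90000000	neutral	-0.001	NA	200	60	0.5	0.5
RB1_P45	3	1	149999999	neutral	0.001	NA	3000	900	0.5	0.5
RB1_P45	3	150000000	160000000	loss	-0.97	1.0	200	60	0.0	1.0
RB1_P45	3	160000001	198000000	neutral	-0.001	NA	760	228	0.5	0.5
RB1_P45	16	1	64999999	neutral	0.001	NA	1300	390	0.5	0.5
RB1_P45	16	65000000	80000000	gain	0.59	1.0	300	90	0.33	0.67
RB1_P45	16	80000001	90000000	neutral	0.002	NA	200	60	0.5	0.5
TP53_P15	1	1	249000000	neutral	0.96	NA	4980	1494	0.5	0.5
TP53_P15	6	1	60000000	neutral	0.97	NA	1200	360	0.5	0.5
TP53_P15	6	60000001	75000000	complex	0.35	NA	300	90	0.18	0.82
TP53_P15	6	75000001	171000000	neutral	0.96	NA	1920	576	0.5	0.5
TP53_P15	8	1	80000000	gain	1.32	0.95	1600	480	0.39	0.61
TP53_P15	8	80000001	145000000	neutral	0.97	NA	1300	390	0.5	0.5
TP53_P15	NA	NA	NA	wgd	NA	0.97	NA	NA	NA	NA
TP53_P30	1	1	249000000	neutral	0.97	NA	4980	1494	0.5	0.5
TP53_P30	6	1	60000000	neutral	0.96	NA	1200	360	0.5	0.5
TP53_P30	6	60000001	75000000	complex	0.34	NA	300	90	0.17	0.83
TP53_P30	6	75000001	171000000	neutral	0.97	NA	1920	576	0.5	0.5
TP53_P30	8	1	80000000	gain	1.33	0.96	1600	480	0.38	0.62
TP53_P30	8	80000001	145000000	neutral	0.96	NA	1300	390	0.5	0.5
TP53_P30	5	1	46000000	loss	0.55	0.52	920	276	0.31	0.69
TP53_P30	NA	NA	NA	wgd	NA	0.98	NA	NA	NA	NA
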